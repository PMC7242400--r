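# Regional and global functional indices derived from the geometry fields:
# curvature-based wall stress index, peak systolic wall stress, area
# strain, per-segment aggregation and global volumetrics.

#' Curvature-based wall stress index
#'
#' sigma_i = R / (2 WT (1 + WT / (2 R))), the thick-walled Laplace form of
#' pressure-normalized wall stress, with R the inner radius of curvature
#' and WT the wall thickness. R is taken as the reciprocal of the
#' endocardial curvedness at each vertex, which is well-defined at umbilic
#' points and reduces to the usual radius on spheres.
#'
#' @param R radius of curvature: an `lv_vertex_field` or numeric (mm), > 0.
#' @param WT wall thickness: an `lv_vertex_field` or numeric (mm), > 0.
#' @return same shape as the inputs (dimensionless); `lv_vertex_field`
#'   when `R` is one.
#' @export
wall_stress_index <- function(R, WT) {
  r <- if (inherits(R, "lv_vertex_field")) R$values else R
  w <- if (inherits(WT, "lv_vertex_field")) WT$values else WT
  if (any(r <= 0, na.rm = TRUE) || any(w <= 0, na.rm = TRUE))
    stop_lv("indices", "R and WT must be strictly positive")
  sig <- r / (2 * w * (1 + w / (2 * r)))
  if (inherits(R, "lv_vertex_field"))
    vertex_field(R$mesh, "stress_index", sig) else sig
}

#' Peak systolic wall stress
#'
#' sigma_ES = 0.133 * SP * sigma_i_ES with SP = 0.9 * systolic blood
#' pressure (mmHg), the peak systolic ventricular pressure surrogate. The
#' 0.133 factor converts mmHg to kN/m^2, so the result is in units of
#' 1000 N/m^2.
#'
#' @param sigma_i_es ES wall stress index (vertex field, per-segment vector
#'   or scalar).
#' @param sbp brachial systolic blood pressure, mmHg.
#' @return same shape as `sigma_i_es`, in 1000 N/m^2.
#' @export
peak_systolic_wall_stress <- function(sigma_i_es, sbp) {
  if (missing(sbp) || is.null(sbp) || is.na(sbp) || !is.numeric(sbp))
    stop_lv("indices", "peak systolic wall stress is undefined without a ",
            "systolic blood pressure")
  if (sbp <= 0) stop_lv("indices", "sbp must be > 0")
  sp <- 0.9 * sbp
  s <- if (inherits(sigma_i_es, "lv_vertex_field")) sigma_i_es$values
       else sigma_i_es
  out <- 0.133 * sp * s
  if (inherits(sigma_i_es, "lv_vertex_field"))
    vertex_field(sigma_i_es$mesh, "peak_systolic_wall_stress", out,
                 "1000 N/m^2") else out
}

#' Endocardial area strain per segment
#'
#' AS = |ln(SA_ES / SA_ED)| * 100 %, the log-ratio of a segment's
#' endocardial surface area between end-systole and end-diastole, reported
#' as a magnitude (contraction shrinks areas, and the index is read as a
#' deformation magnitude).
#'
#' @param sa_ed,sa_es per-segment endocardial areas (mm^2), same labeling
#'   carried across phases through the vertex correspondence.
#' @return per-segment area strain, %.
#' @export
area_strain <- function(sa_ed, sa_es) {
  if (any(sa_ed <= 0) || any(sa_es <= 0))
    stop_lv("indices", "segment areas must be strictly positive")
  abs(log(sa_es / sa_ed)) * 100
}

#' Compute the full regional parameter set for one subject
#'
#' Per segment: mean curvedness and wall thickness over assigned interior
#' vertices at ED and ES; wall stress index from per-vertex R = 1/C and WT,
#' then segment-averaged; peak systolic wall stress from the segment ES
#' stress index and the subject's systolic pressure; area strain from the
#' segment areas. The subject aggregate (`segment = "all"`) is the
#' unweighted mean of the 16 segment values.
#'
#' @param pair_endo,pair_epi corresponded `lv_mesh_pair`s from
#'   [build_mesh_pair()].
#' @param labeling an `lv_segment_labeling` on the ED endocardial mesh.
#' @param subject list or one-row data frame with at least `sbp` (mmHg);
#'   `subject_id` optional.
#' @param ring_depth curvature neighbourhood depth.
#' @return tibble with one row per segment plus an `"all"` row; columns
#'   `C_ED`, `C_ES` (mm^-1), `WT_ED`, `WT_ES` (mm), `sigma_i_ED`,
#'   `sigma_i_ES`, `sigma_ES` (1000 N/m^2), `AS` (%), `SA_ED`, `SA_ES`
#'   (mm^2).
#' @export
compute_regional_parameters <- function(pair_endo, pair_epi, labeling,
                                        subject, ring_depth = 2L) {
  subject <- as.list(subject)
  phase_fields <- function(endo, epi) {
    ks <- principal_curvatures(endo, ring_depth)
    C <- curvedness(ks$k1, ks$k2)
    WT <- wall_thickness_map(endo, epi)
    ok <- !is.na(C$values) & !is.na(WT$values) & C$values > 0
    sig <- rep(NA_real_, length(C$values))
    sig[ok] <- wall_stress_index(1 / C$values[ok], WT$values[ok])
    list(C = C, WT = WT,
         sigma = vertex_field(endo, "stress_index", sig))
  }
  ed <- phase_fields(pair_endo$ed, pair_epi$ed)
  es <- phase_fields(pair_endo$es, pair_epi$es)
  sa_ed <- segment_areas(pair_endo$ed, labeling)
  sa_es <- segment_areas(pair_endo$es, labeling)
  res <- tibble::tibble(
    subject_id = subject$subject_id %||% "subject",
    segment = as.character(1:16),
    C_ED = segment_means(ed$C, labeling),
    C_ES = segment_means(es$C, labeling),
    WT_ED = segment_means(ed$WT, labeling),
    WT_ES = segment_means(es$WT, labeling),
    sigma_i_ED = segment_means(ed$sigma, labeling),
    sigma_i_ES = segment_means(es$sigma, labeling),
    SA_ED = sa_ed, SA_ES = sa_es)
  res$sigma_ES <- peak_systolic_wall_stress(res$sigma_i_ES, subject$sbp)
  res$AS <- area_strain(res$SA_ED, res$SA_ES)
  agg <- res[1, ]
  agg$segment <- "all"
  num <- c("C_ED", "C_ES", "WT_ED", "WT_ES", "sigma_i_ED", "sigma_i_ES",
           "SA_ED", "SA_ES", "sigma_ES", "AS")
  for (cn in num) agg[[cn]] <- mean(res[[cn]])
  rbind(res, agg)
}

#' Global LV function metrics from the reconstructed meshes
#'
#' EDV and ESV are basally-capped chamber volumes of the endocardial
#' meshes; SV = EDV - ESV; EF = 100 SV / EDV; LV mass = (epicardial ED
#' volume - endocardial ED volume) * 1.05 g/ml. Indices are divided by
#' body surface area.
#'
#' @param ed_endo,es_endo,ed_epi `lv_surface_mesh`es.
#' @param subject list/row with `height` (cm) and `weight` (kg), or `bsa`
#'   (m^2) directly.
#' @return tibble with EDV, ESV, SV (ml), EF (%), mass (g), BSA-indexed
#'   variants (ml/m^2, g/m^2) and mass-to-volume ratio (g/ml).
#' @export
global_function_metrics <- function(ed_endo, es_endo, ed_epi, subject) {
  subject <- as.list(subject)
  bsa <- subject$bsa %||% bsa_mosteller(subject$height, subject$weight)
  edv <- chamber_volume(ed_endo) / 1000
  esv <- chamber_volume(es_endo) / 1000
  if (esv >= edv)
    warning("ESV >= EDV: possible ED/ES phase mislabel", call. = FALSE)
  sv <- edv - esv
  ef <- 100 * sv / edv
  mass <- 1.05 * (chamber_volume(ed_epi) / 1000 - edv)
  tibble::tibble(
    subject_id = subject$subject_id %||% "subject",
    EDV = edv, ESV = esv, SV = sv, EF = ef, mass = mass,
    EDV_index = edv / bsa, ESV_index = esv / bsa, SV_index = sv / bsa,
    mass_index = mass / bsa, mass_to_volume = mass / edv, bsa = bsa)
}
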