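#' Region labels used in the cohort analysis
#'
#' Six classes: contrast-enhancing tumor, T2-hyperintense tissue,
#' normal-appearing tissue adjacent to the T2-hyperintense area, more
#' distant normal-appearing tissue on the ipsilateral hemisphere, the
#' contralateral hemisphere, and healthy-volunteer brain.
#'
#' @return Character vector of the six region labels.
#' @export
region_levels <- function() {
  c("contrast_enhancing", "t2_hyperintense", "adjacent",
    "distant_ipsilateral", "contralateral", "healthy_volunteer")
}

#' Voxel inclusion rules
#'
#' A voxel enters the analysis only when more than two-thirds of it is the
#' desired tissue, and it is excluded when necrosis takes up more than one
#' third -- both read as strict inequalities, so a voxel at exactly 2/3
#' desired tissue is excluded. The decision is recorded per row in the
#' `included` flag with a `qc_reason` (`"ok"`, `"tissue_fraction"`,
#' `"necrosis"`; a voxel failing both rules reports `"necrosis"` first).
#' Applying the rules twice changes nothing.
#'
#' @param voxels A data frame with numeric columns `frac_desired` and
#'   (optionally) `frac_necrosis`, one row per voxel; typically a cohort
#'   table from [generate_cohort()]. All fractions must lie in \[0, 1\] and
#'   the disjoint compartments (`frac_desired`, `frac_csf`, `frac_bone`)
#'   must sum to at most 1 per voxel. `frac_necrosis` may overlap
#'   `frac_desired`: a necrotic tumor core is still tumor tissue, which is
#'   exactly why a heavily necrotic voxel is excluded even when the desired
#'   tissue dominates it.
#' @return The input tibble with `included` and `qc_reason` columns
#'   (re)computed.
#' @examples
#' apply_inclusion_rules(tibble::tibble(frac_desired = c(0.7, 0.8, 2 / 3),
#'                                      frac_necrosis = c(0.1, 0.4, 0)))
#' @export
apply_inclusion_rules <- function(voxels) {
  if (!is.data.frame(voxels) || !"frac_desired" %in% names(voxels)) {
    abort("`voxels` must be a data frame with a `frac_desired` column.")
  }
  voxels <- as_tibble(voxels)
  if (!"frac_necrosis" %in% names(voxels)) voxels$frac_necrosis <- 0
  comp <- intersect(c("frac_desired", "frac_necrosis", "frac_csf", "frac_bone"),
                    names(voxels))
  fr <- as.matrix(voxels[comp])
  if (any(fr < 0 | fr > 1)) abort("Tissue fractions must lie in [0, 1].")
  disjoint <- setdiff(comp, "frac_necrosis")
  if (any(rowSums(as.matrix(voxels[disjoint])) > 1 + 1e-8)) {
    abort("Tissue fractions must sum to at most 1 per voxel.")
  }
  voxels %>%
    mutate(
      qc_reason = case_when(
        .data$frac_necrosis > 1 / 3 ~ "necrosis",
        .data$frac_desired <= 2 / 3 ~ "tissue_fraction",
        TRUE ~ "ok"
      ),
      included = .data$qc_reason == "ok"
    )
}

#' Summarise exclusions of a cohort
#'
#' @param cohort A table that has passed [apply_inclusion_rules()] (columns
#'   `included`, `qc_reason`).
#' @return A list with `total`, `n_included`, `n_excluded`,
#'   `fraction_excluded` and a `by_reason` tibble.
#' @export
exclusion_summary <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    abort("`cohort` must be a non-empty data frame.")
  }
  if (!all(c("included", "qc_reason") %in% names(cohort))) {
    abort("Run `apply_inclusion_rules()` first.")
  }
  n <- nrow(cohort)
  n_ex <- sum(!cohort$included)
  by_reason <- cohort %>%
    filter(!.data$included) %>%
    dplyr::count(.data$qc_reason, name = "n") %>%
    mutate(fraction = .data$n / !!n)
  list(
    total = n,
    n_included = n - n_ex,
    n_excluded = n_ex,
    fraction_excluded = n_ex / n,
    by_reason = by_reason
  )
}
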