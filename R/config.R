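#' Category vocabularies
#'
#' The closed vocabularies used by the readers and the analysis
#' functions. `microhabitat_categories()` lists the nine substrate and
#' vegetation classes scored in 20 x 20 m quadrats of a high-Andean
#' *Polylepis* woodland (two of which, dry organic matter and the
#' Asteraceae shrub *Nordenstamia longistyla*, are typically unused by
#' the lizards and dropped before selection analysis).
#' `prey_categories()` lists the arthropod (plus mollusc and plant
#' material) categories distinguished in stomach contents and pitfall
#' catches, mostly at family level.
#'
#' Both vocabularies can be extended at read time via
#' `allow_new_categories = TRUE` in the readers, since real deployments
#' add categories.
#'
#' @return A character vector of category identifiers.
#' @export
#' @examples
#' microhabitat_categories()
microhabitat_categories <- function() {
  c("polylepis_tree", "scrubland", "thorny_bush", "nonthorny_bush",
    "rock", "small_rock", "uncovered_land", "dry_organic_matter",
    "nordenstamia_longistyla")
}

#' @rdname microhabitat_categories
#' @export
prey_categories <- function() {
  c("Lygaeidae", "Acari", "Araneae", "Sphecidae", "Solifugae",
    "Anthomyiidae", "Coccinelidae", "Asilidae", "Larvae_worms",
    "Formicidae", "Curculionidae", "Hymenoptera_indet", "Apoidea",
    "Cicadelidae", "Tephritidae", "Drosophilidae", "Diptera_indet",
    "Noctuiidae", "Tabanidae", "Tachinidae", "Empididae", "Halictidae",
    "Ichneumonidae", "Miridae", "Hemiptera_indet", "Licenidae",
    "Mollusca", "Trichoptera", "plant_material")
}

#' Study-level analysis configuration
#'
#' Bundles the knobs shared across the pipeline: the family-wise error
#' level, how many comparisons enter the Bonferroni adjustment, which
#' confidence-interval multiplier convention to use, the denominator
#' convention for diet frequency percentages, the permutation count for
#' distance-based tests, the kernel bandwidth for activity curves, and
#' the display rounding profile.
#'
#' @param alpha Family-wise error level in (0, 1). Default 0.05.
#' @param n_resources `"auto"` (count retained categories at analysis
#'   time) or a positive integer fixing the number of comparisons `I`
#'   in the Bonferroni adjustment.
#' @param ci_convention `"textbook"` (normal quantile at
#'   `1 - alpha/(2I)`) or `"paper_compat"` (quantile at `1 - alpha/I`;
#'   see [bonferroni_ci()]).
#' @param freq_denominator `"stomachs"` (percent frequency over the
#'   number of stomachs) or `"total_item_frequency"` (over the summed
#'   category frequencies); see [diet_table()].
#' @param n_permutations Positive integer; permutations for
#'   [permanova()] and [dispersion_homogeneity()]. Default 9999.
#' @param rng_seed Integer seed recorded with the configuration.
#' @param kde_bandwidth Gaussian kernel standard deviation in hours for
#'   [kde_activity()]. Default 1/3.
#' @param rounding Named list with elements `percentages` and `ratios`,
#'   decimal places used by [write_report()] for display only.
#'
#' @return A list of class `"study_config"`.
#' @export
#' @examples
#' cfg <- study_config(alpha = 0.05, n_permutations = 999)
#' cfg$kde_bandwidth
study_config <- function(alpha = 0.05,
                         n_resources = "auto",
                         ci_convention = c("textbook", "paper_compat"),
                         freq_denominator = c("stomachs", "total_item_frequency"),
                         n_permutations = 9999,
                         rng_seed = 1L,
                         kde_bandwidth = 1 / 3,
                         rounding = list(percentages = 1, ratios = 3)) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  if (!identical(n_resources, "auto")) {
    if (!is.numeric(n_resources) || n_resources < 1 ||
        n_resources != round(n_resources)) {
      abort("`n_resources` must be \"auto\" or a positive integer.")
    }
    n_resources <- as.integer(n_resources)
  }
  if (!is.numeric(n_permutations) || n_permutations < 1) {
    abort("`n_permutations` must be >= 1.")
  }
  if (!is.numeric(kde_bandwidth) || kde_bandwidth <= 0) {
    abort("`kde_bandwidth` must be > 0.")
  }
  structure(
    list(
      alpha = alpha,
      n_resources = n_resources,
      ci_convention = match.arg(ci_convention),
      freq_denominator = match.arg(freq_denominator),
      n_permutations = as.integer(n_permutations),
      rng_seed = as.integer(rng_seed),
      kde_bandwidth = kde_bandwidth,
      rounding = rounding
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  alpha:", x$alpha, " n_resources:", as.character(x$n_resources), "\n")
  cat("  ci_convention:", x$ci_convention,
      " freq_denominator:", x$freq_denominator, "\n")
  cat("  n_permutations:", x$n_permutations,
      " kde_bandwidth:", x$kde_bandwidth, "h\n")
  invisible(x)
}

# run a block with a fixed seed without disturbing the caller's RNG;
# seed = NULL leaves the RNG stream alone
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}
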