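#' Diet importance table from aggregated category totals
#'
#' Builds the full importance table from per-category totals: item
#' count `N`, number of stomachs containing the category `F`, and
#' summed dry weight `W` (grams). Percentages are taken over the
#' animal categories; `%F` divides by the number of stomachs under the
#' `"stomachs"` convention (the standard definition) or by the summed
#' frequency `sum(F)` under `"total_item_frequency"` (a dialect some
#' pooled tables use). The index of relative importance is
#' `IRI = (%N + %W) * %F`, and `%IRI` is each category's share of the
#' IRI sum. Each category receives a dietary-hierarchy label via
#' [classify_hierarchy()].
#'
#' Plant material never enters the importance table; pass its total
#' dry weight through `plant_weight_g` to obtain the table-level plant
#' `%W` (plant mass over plant plus animal mass) and the diet-mode
#' label via [diet_mode()].
#'
#' @param counts Named vector of item counts `N` per animal category.
#' @param frequencies Named vector `F` (stomachs containing each
#'   category), aligned with `counts`.
#' @param weights Named vector `W` of summed dry weights (g).
#' @param n_stomachs Number of stomachs examined.
#' @param plant_weight_g Total plant-material dry weight (g), default
#'   0.
#' @param freq_denominator `"stomachs"` or `"total_item_frequency"`.
#'
#' @return A tibble of class `"diet_table"` with columns
#'   `prey_category, n, pct_n, f, pct_f, w, pct_w, iri, pct_iri,
#'   hierarchy` and attributes `n_stomachs`, `plant_pct_w`,
#'   `diet_mode`.
#' @export
#' @examples
#' diet_table(counts = c(Lygaeidae = 76, Acari = 38),
#'            frequencies = c(Lygaeidae = 13, Acari = 4),
#'            weights = c(Lygaeidae = 0.0079, Acari = 0.0005),
#'            n_stomachs = 14)
diet_table <- function(counts, frequencies, weights, n_stomachs,
                       plant_weight_g = 0,
                       freq_denominator = c("stomachs",
                                            "total_item_frequency")) {
  freq_denominator <- match.arg(freq_denominator)
  if (n_stomachs < 1) abort("no stomachs")
  cats <- names(counts)
  if (is.null(cats)) abort("category totals must be named")
  frequencies <- frequencies[cats]
  weights <- weights[cats]
  if (any(is.na(frequencies)) || any(is.na(weights))) {
    abort("counts, frequencies and weights must share categories")
  }
  if (any(frequencies > n_stomachs)) {
    abort("F cannot exceed the number of stomachs")
  }
  if (sum(weights) <= 0) abort("zero total prey weight; %W undefined")

  pct_n <- 100 * counts / sum(counts)
  denom <- switch(freq_denominator,
                  stomachs = n_stomachs,
                  total_item_frequency = sum(frequencies))
  pct_f <- 100 * frequencies / denom
  pct_w <- 100 * weights / sum(weights)
  iri <- (pct_n + pct_w) * pct_f
  pct_iri <- 100 * iri / sum(iri)

  out <- tibble::tibble(
    prey_category = cats,
    n = as.numeric(counts),
    pct_n = as.numeric(pct_n),
    f = as.numeric(frequencies),
    pct_f = as.numeric(pct_f),
    w = as.numeric(weights),
    pct_w = as.numeric(pct_w),
    iri = as.numeric(iri),
    pct_iri = as.numeric(pct_iri),
    hierarchy = classify_hierarchy(as.numeric(pct_iri))
  )
  class(out) <- c("diet_table", class(out))
  plant_pct_w <- 100 * plant_weight_g / (plant_weight_g + sum(weights))
  attr(out, "n_stomachs") <- as.integer(n_stomachs)
  attr(out, "plant_pct_w") <- plant_pct_w
  attr(out, "diet_mode") <- diet_mode(plant_pct_w)
  out
}

#' Tabulate stomach contents into a diet table
#'
#' Aggregates per-individual stomach records (one row per individual
#' and prey category, as read by [read_stomachs()]) into category
#' totals and delegates to [diet_table()]. Plant-material rows are
#' excluded from the count-based columns but their mass enters the
#' table-level plant `%W` and diet-mode classification. Individuals
#' with no animal items still count toward the stomach total.
#'
#' @param stomachs Tibble with columns `individual_id, prey_category,
#'   count, dry_weight_g` (a `site` column, if present, is ignored:
#'   filter beforehand to analyse one site).
#' @inheritParams diet_table
#' @return A `"diet_table"`; see [diet_table()].
#' @export
tabulate_diet <- function(stomachs,
                          freq_denominator = c("stomachs",
                                               "total_item_frequency")) {
  x <- tibble::as_tibble(stomachs)
  if (nrow(x) == 0 || length(unique(x$individual_id)) == 0) {
    abort("no stomachs")
  }
  n_stomachs <- length(unique(x$individual_id))
  plant <- x$prey_category == "plant_material"
  plant_weight <- sum(x$dry_weight_g[plant], na.rm = TRUE)
  animal <- x[!plant & !is.na(x$prey_category), , drop = FALSE]
  if (nrow(animal) == 0) abort("no animal prey items in any stomach")
  agg <- animal |>
    dplyr::group_by(.data$prey_category) |>
    dplyr::summarise(
      n = sum(.data$count),
      f = dplyr::n_distinct(.data$individual_id),
      w = sum(.data$dry_weight_g),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n))
  diet_table(
    counts = setNames(agg$n, agg$prey_category),
    frequencies = setNames(agg$f, agg$prey_category),
    weights = setNames(agg$w, agg$prey_category),
    n_stomachs = n_stomachs,
    plant_weight_g = plant_weight,
    freq_denominator = freq_denominator
  )
}

#' @export
glance.diet_table <- function(x, ...) {
  tibble::tibble(
    n_stomachs = attr(x, "n_stomachs"),
    n_categories = nrow(x),
    plant_pct_w = attr(x, "plant_pct_w"),
    diet_mode = attr(x, "diet_mode")
  )
}

#' Dietary hierarchy from %IRI
#'
#' Labels prey categories by their share of relative importance:
#' fundamental (> 75%), secondary (50-75%), accessory (25-50%) and
#' accidental (<= 25%). Band boundaries close on the lower band.
#'
#' @param pct_iri Numeric vector of %IRI values in \[0, 100].
#' @return Character vector of labels.
#' @export
#' @examples
#' classify_hierarchy(c(62.9, 44.8, 3.1, 100))
classify_hierarchy <- function(pct_iri) {
  dplyr::case_when(
    pct_iri > 75 ~ "fundamental",
    pct_iri > 50 ~ "secondary",
    pct_iri > 25 ~ "accessory",
    .default = "accidental"
  )
}

#' Diet-mode classification from plant %W
#'
#' Classifies a diet by the weight share of plant material:
#' insectivorous (0-10%), omnivorous (10-50%), herbivorous (50-100%).
#' Boundary values close on the lower band.
#'
#' @param plant_pct_w Plant-material weight percentage in \[0, 100].
#' @return Character vector of labels.
#' @export
#' @examples
#' diet_mode(c(47.924, 68.865, 0))
diet_mode <- function(plant_pct_w) {
  dplyr::case_when(
    plant_pct_w > 50 ~ "herbivorous",
    plant_pct_w > 10 ~ "omnivorous",
    .default = "insectivorous"
  )
}

#' Standardized Levins niche breadth
#'
#' `Ba = (1/sum(p_i^2) - 1) / (n - 1)` on diet proportions `p_i`, with
#' `n` the number of prey categories in the universe: 0 for a
#' single-category diet, 1 for uniform use of all `n` categories.
#' Under the `"averaged"` method each individual's own category
#' proportions are averaged across individuals before computing the
#' index (damping the influence of individuals with many items); under
#' `"aggregated"` the proportions come from pooled counts.
#'
#' @param x Either a stomachs tibble (`individual_id, prey_category,
#'   count`) or a numeric vector of proportions/counts.
#' @param method `"averaged"` or `"aggregated"`; ignored when `x` is a
#'   plain vector.
#' @param n_categories Size of the category universe; defaults to the
#'   number of categories observed (with positive proportion).
#' @return Ba in \[0, 1].
#' @export
#' @examples
#' levins_breadth(c(0.5, 0.5))       # 1
#' levins_breadth(c(1, 0, 0))        # 0
levins_breadth <- function(x, method = c("averaged", "aggregated"),
                           n_categories = NULL) {
  method <- match.arg(method)
  if (is.data.frame(x)) {
    animal <- x[x$prey_category != "plant_material" &
                  !is.na(x$count), , drop = FALSE]
    wide <- animal |>
      dplyr::group_by(.data$individual_id, .data$prey_category) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "prey_category",
                         values_from = "count", values_fill = 0)
    mat <- as.matrix(wide[, -1, drop = FALSE])
    p <- if (method == "averaged") {
      colMeans(mat / rowSums(mat))
    } else {
      colSums(mat) / sum(mat)
    }
  } else {
    p <- x / sum(x)
  }
  p <- p[p > 0]
  n <- n_categories %||% length(p)
  if (n <= 1) return(0)
  p <- p / sum(p)
  (1 / sum(p^2) - 1) / (n - 1)
}

#' Pianka niche overlap
#'
#' `O = sum(p_j p_k) / sqrt(sum(p_j^2) sum(p_k^2))` over the union of
#' categories (absent categories contribute 0). Symmetric, invariant
#' to rescaling either vector, 0 for disjoint and 1 for identical
#' resource use.
#'
#' @param p_j,p_k Numeric vectors of proportions or counts; when
#'   named, categories are aligned over the union of names.
#' @return Overlap in \[0, 1].
#' @export
#' @examples
#' pianka_overlap(c(a = 1, b = 1), c(a = 2, b = 2))  # 1
pianka_overlap <- function(p_j, p_k) {
  if (!is.null(names(p_j)) && !is.null(names(p_k))) {
    cats <- union(names(p_j), names(p_k))
    p_j <- setNames(ifelse(is.na(p_j[cats]), 0, p_j[cats]), cats)
    p_k <- setNames(ifelse(is.na(p_k[cats]), 0, p_k[cats]), cats)
  } else if (length(p_j) != length(p_k)) {
    abort("unnamed vectors must have equal length")
  }
  p_j <- p_j / sum(p_j)
  p_k <- p_k / sum(p_k)
  sum(p_j * p_k) / sqrt(sum(p_j^2) * sum(p_k^2))
}

#' Hill effective number of species
#'
#' Diversity of order `q` expressed as an effective species count:
#' `D = (sum p_i^q)^(1/(1-q))`, with the `q = 1` limit
#' `exp(-sum p_i log p_i)` (the exponential of Shannon entropy). Equals
#' the species count for a perfectly even community at any order.
#'
#' @param counts Abundances (or proportions) per species.
#' @param q Diversity order, default 1.
#' @return Effective number of species (>= 1 for any nonempty
#'   community).
#' @export
#' @examples
#' hill_effective_species(rep(5, 10))      # 10
#' hill_effective_species(c(50, 25, 25))   # 2.828
hill_effective_species <- function(counts, q = 1) {
  p <- counts[counts > 0]
  if (length(p) == 0) abort("empty community")
  p <- p / sum(p)
  if (abs(q - 1) < 1e-9) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Prey selection against pitfall availability
#'
#' Treats each prey category as a food resource: diet item counts give
#' proportional use and pitfall relative abundances give availability,
#' then the full Type I selection analysis ([selection_analysis()])
#' runs over the categories shared between diet and pitfalls. Diet
#' categories missing from the pitfall catches cannot be scored and
#' are reported with a warning; availability is renormalized over the
#' shared set.
#'
#' @param diet A `"diet_table"` (or tibble with `prey_category` and
#'   `n` columns).
#' @param pitfalls Pitfall tibble (`prey_category, count`, e.g. from
#'   [read_pitfalls()]) or a named count vector.
#' @inheritParams selection_analysis
#' @return A `"selection_table"` over the shared prey categories, with
#'   attribute `unscored` listing diet categories absent from the
#'   pitfalls.
#' @export
prey_selection <- function(diet, pitfalls, alpha = 0.05,
                           ci_convention = c("textbook", "paper_compat"),
                           drop_unused = TRUE) {
  use <- setNames(as.integer(round(diet$n)), diet$prey_category)
  if (is.data.frame(pitfalls)) {
    avail_counts <- tapply(pitfalls$count, pitfalls$prey_category, sum)
    avail_counts <- setNames(as.numeric(avail_counts), names(avail_counts))
  } else {
    avail_counts <- pitfalls
  }
  avail_counts <- avail_counts[avail_counts > 0]
  unscored <- setdiff(names(use), names(avail_counts))
  if (length(unscored) > 0) {
    warn(paste0("diet categories absent from pitfalls, not scored: ",
                paste(unscored, collapse = ", ")))
    use <- use[setdiff(names(use), unscored)]
  }
  avail <- avail_counts[names(use)]
  avail <- avail / sum(avail)
  out <- selection_analysis(use, avail, alpha = alpha,
                            ci_convention = ci_convention,
                            drop_unused = drop_unused)
  attr(out, "unscored") <- unscored
  out
}
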