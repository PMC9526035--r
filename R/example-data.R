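#' Worked-example data: microhabitat selection summary
#'
#' Published-style summary data from a two-site field study of the
#' Andean lizard *Liolaemus etheridgei* in *Polylepis* woodland
#' (sites "El Simbral" and "Tuctumpaya", plus the pooled sample of 168
#' encounters). Per microhabitat and site the table carries the
#' availability proportion (crown-diameter estimate over 30 quadrats
#' per site), the proportional use, and the reported standard error of
#' the selection ratio. Only the seven microhabitats with nonzero use
#' are included (two further categories, dry organic matter and
#' *Nordenstamia longistyla*, were never used and are dropped before
#' analysis, which is why the Bonferroni family size is 7).
#'
#' The `se` column is the study's reported value, retained so that
#' published simultaneous confidence bounds can be reproduced with
#' [bonferroni_ci()]; it is larger than the known-availability
#' closed-form standard error because availability was itself
#' estimated in the field.
#'
#' @return A tibble `site, category, available, used, se`.
#' @seealso [encounter_counts_example()], [diet_example()]
#' @export
#' @examples
#' x <- microhabitat_example()
#' pooled <- subset(x, site == "pooled")
#' round(pooled$used / pooled$available, 3)
microhabitat_example <- function() {
  cats <- c("polylepis_tree", "scrubland", "thorny_bush",
            "nonthorny_bush", "rock", "small_rock", "uncovered_land")
  dplyr::bind_rows(
    tibble::tibble(
      site = "pooled", category = cats,
      available = c(0.351, 0.155, 0.096, 0.081, 0.057, 0.200, 0.060),
      used = c(0.149, 0.095, 0.077, 0.012, 0.065, 0.357, 0.244),
      se = c(0.125, 0.251, 0.393, 0.154, 0.674, 0.443, 1.810)
    ),
    tibble::tibble(
      site = "el_simbral", category = cats,
      available = c(0.293, 0.159, 0.147, 0.059, 0.087, 0.200, 0.056),
      used = c(0.119, 0.136, 0.153, 0.017, 0.068, 0.407, 0.102),
      se = c(0.157, 0.344, 0.407, 0.308, 0.455, 0.520, 1.031)
    ),
    tibble::tibble(
      site = "tuctumpaya", category = cats,
      available = c(0.409, 0.152, 0.046, 0.103, 0.027, 0.201, 0.063),
      used = c(0.165, 0.073, 0.037, 0.009, 0.064, 0.330, 0.321),
      se = c(0.100, 0.200, 0.539, 0.093, 1.704, 0.398, 2.072)
    )
  )
}

#' Worked-example data: encounter counts per site
#'
#' Per-microhabitat encounter counts reconstructed from the reported
#' use proportions and site totals (El Simbral 59, Tuctumpaya 109,
#' pooled 168) of the same field study as [microhabitat_example()].
#'
#' @return A tibble `site, category, count`.
#' @export
#' @examples
#' sum(encounter_counts_example()$count)  # 2 * 168 (sites + pooled)
encounter_counts_example <- function() {
  cats <- c("polylepis_tree", "scrubland", "thorny_bush",
            "nonthorny_bush", "rock", "small_rock", "uncovered_land")
  dplyr::bind_rows(
    tibble::tibble(site = "pooled", category = cats,
                   count = c(25L, 16L, 13L, 2L, 11L, 60L, 41L)),
    tibble::tibble(site = "el_simbral", category = cats,
                   count = c(7L, 8L, 9L, 1L, 4L, 24L, 6L)),
    tibble::tibble(site = "tuctumpaya", category = cats,
                   count = c(18L, 8L, 4L, 1L, 7L, 36L, 35L))
  )
}

#' Worked-example data: diet composition totals
#'
#' Per-category stomach-content totals (item count `n`, number of
#' stomachs containing the category `f`, summed dry weight `w` in
#' grams) for the two sites of the same field study (14 stomachs in
#' El Simbral, 19 in Tuctumpaya, 33 pooled), animal categories only.
#' Feeding these totals to [diet_table()] reproduces the published
#' percentage and importance-index columns.
#'
#' @return A tibble `site, prey_category, n, f, w` with attribute
#'   `n_stomachs` (named vector per site).
#' @export
#' @examples
#' d <- subset(diet_example(), site == "el_simbral")
#' dt <- diet_table(setNames(d$n, d$prey_category),
#'                  setNames(d$f, d$prey_category),
#'                  setNames(d$w, d$prey_category), n_stomachs = 14)
#' dt[dt$prey_category == "Lygaeidae", "pct_iri"]  # ~62.9
diet_example <- function() {
  es <- tibble::tibble(
    site = "el_simbral",
    prey_category = c("Lygaeidae", "Acari", "Araneae", "Sphecidae",
                      "Solifugae", "Anthomyiidae", "Coccinelidae",
                      "Asilidae", "Larvae_worms", "Formicidae",
                      "Curculionidae", "Hymenoptera_indet", "Apoidea",
                      "Cicadelidae", "Tephritidae", "Drosophilidae",
                      "Diptera_indet"),
    n = c(76, 38, 4, 11, 5, 4, 7, 2, 4, 2, 1, 3, 1, 1, 1, 1, 1),
    f = c(13, 4, 4, 6, 3, 3, 3, 2, 3, 1, 1, 1, 1, 1, 1, 1, 1),
    w = c(0.0079, 0.0005, 0.0200, 0.0013, 0.0100, 0.0100, 0.0042,
          0.0140, 0.0030, 0.0160, 0.0070, 0.0040, 0.0005, 0.0003,
          0.0002, 0.0001, 0.0000)
  )
  tu <- tibble::tibble(
    site = "tuctumpaya",
    prey_category = c("Lygaeidae", "Acari", "Araneae", "Sphecidae",
                      "Solifugae", "Anthomyiidae", "Coccinelidae",
                      "Asilidae", "Larvae_worms", "Hymenoptera_indet",
                      "Cicadelidae", "Diptera_indet", "Noctuiidae",
                      "Tabanidae", "Tachinidae", "Empididae",
                      "Halictidae", "Ichneumonidae", "Miridae",
                      "Hemiptera_indet", "Licenidae", "Mollusca",
                      "Trichoptera"),
    n = c(82, 21, 8, 8, 4, 13, 14, 2, 18, 1, 3, 13, 5, 4, 10, 13, 5,
          2, 1, 1, 1, 1, 1),
    f = c(17, 10, 6, 6, 2, 7, 7, 2, 7, 1, 3, 2, 4, 4, 4, 5, 2, 2, 1,
          1, 1, 1, 1),
    w = c(0.0085, 0.0003, 0.0400, 0.0009, 0.0080, 0.0325, 0.0084,
          0.0140, 0.0160, 0.0040, 0.0009, 0.0040, 0.1040, 0.0960,
          0.0800, 0.0000, 0.0200, 0.0000, 0.0001, 0.0000, 0.0000,
          0.0000, 0.0000)
  )
  pooled <- dplyr::bind_rows(es, tu) |>
    dplyr::group_by(.data$prey_category) |>
    dplyr::summarise(n = sum(.data$n), f = sum(.data$f),
                     w = sum(.data$w), .groups = "drop") |>
    dplyr::mutate(site = "pooled", .before = 1)
  out <- dplyr::bind_rows(es, tu, pooled)
  attr(out, "n_stomachs") <- c(el_simbral = 14L, tuctumpaya = 19L,
                               pooled = 33L)
  out
}
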