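# shared scenario builders for the simulation-based tests

neutral_scenario <- function(seed, n = 168) {
  a <- c(a = 0.351, b = 0.155, c = 0.096, d = 0.081, e = 0.057,
         f = 0.200, g = 0.060)
  selection_scenario(
    availability = a,
    selection_weights = setNames(rep(1, length(a)), names(a)),
    n_encounters = n, seed = seed
  )
}

pooled_example <- function(site_name) {
  mh <- microhabitat_example()
  ec <- encounter_counts_example()
  p <- mh[mh$site == site_name, ]
  cnt <- ec[ec$site == site_name, ]
  list(available = setNames(p$available, p$category),
       used = setNames(p$used, p$category),
       se = setNames(p$se, p$category),
       counts = setNames(cnt$count, cnt$category))
}

diet_site_vectors <- function(site_name) {
  d <- diet_example()
  d <- d[d$site == site_name, ]
  list(n = setNames(d$n, d$prey_category),
       f = setNames(d$f, d$prey_category),
       w = setNames(d$w, d$prey_category),
       n_stomachs = attr(diet_example(), "n_stomachs")[[site_name]])
}
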