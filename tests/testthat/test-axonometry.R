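# Axon segmentation, size distributions, and the two-factor group
# comparison across the calibre spectrum.

test_that("zero-noise nerve phantoms are segmented to the exact count", {
  np <- generate_nerve_phantom(nerve_phantom_spec(
    n_axons = 40, image_size_px = c(256, 256), psf_sigma_um = 0,
    noise = no_noise, seed = 5))
  tab <- measure_axons(np$image)
  expect_identical(nrow(tab), nrow(np$truth))
  expect_identical(sum(tab$is_motor), sum(np$truth$is_motor))
  expect_equal(sum(tab$csa_um2), sum(np$truth$csa_um2), tolerance = 0.05)
})

test_that("a blank channel yields no axons", {
  img <- plane_image(array(0, c(2, 64, 64)), 0.25, c(bIII = 1L, chat = 2L))
  expect_warning(tab <- measure_axons(img), "no foreground")
  expect_identical(nrow(tab), 0L)
})

test_that("two tangent discs are split by the watershed", {
  m <- matrix(0, 80, 80)
  rr <- row(m); cc <- col(m)
  m[(rr - 40)^2 + (cc - 28)^2 <= 12^2] <- 0.8
  m[(rr - 40)^2 + (cc - 53)^2 <= 12^2] <- 0.8  # tangent to the first
  seg <- segment_axons(m, pixel_size_um = 0.25, min_area_um2 = 0.5)
  expect_identical(length(setdiff(unique(as.vector(seg$labels)), 0L)), 2L)
})

test_that("binning uses right-open intervals and conserves counts", {
  tab <- data.frame(csa_um2 = c(1, 2, 3))
  d <- build_size_distribution(tab, bin_edges = c(0, 2, 4))
  expect_equal(d$counts, c(1, 2))
  expect_identical(d$underflow + d$overflow, 0L)

  tab2 <- data.frame(csa_um2 = c(-1, 0.5, 3.9, 4, 100))
  d2 <- build_size_distribution(tab2, bin_edges = c(0, 2, 4))
  expect_identical(sum(d2$counts) + d2$underflow + d2$overflow, 5L)
  expect_identical(d2$underflow, 1L)
  expect_identical(d2$overflow, 2L)  # 4 falls outside the right-open range

  empty <- build_size_distribution(data.frame(csa_um2 = numeric()),
                                   bin_edges = c(0, 2, 4))
  expect_equal(empty$counts, c(0, 0))
  expect_error(build_size_distribution(tab, bin_edges = c(0, 2, 2)),
               "strictly increasing")
})

test_that("motor counts never exceed total counts in any bin", {
  np <- generate_nerve_phantom(nerve_phantom_spec(n_axons = 200, seed = 9,
                                                  image_size_px = c(900, 900)),
                               raster = FALSE)
  edges <- seq(0, 100, by = 5)
  tot <- build_size_distribution(np$truth, edges, subset = "total")
  mot <- build_size_distribution(np$truth, edges, subset = "motor")
  expect_true(all(mot$counts <= tot$counts))
})

test_that("sampled histograms match the analytic mixture CDF", {
  mix <- list(meanlog = c(log(4), log(25)), sdlog = c(0.6, 0.35),
              weight = c(0.65, 0.35))
  np <- generate_nerve_phantom(nerve_phantom_spec(
    n_axons = 1000, calibre_mixture = mix,
    image_size_px = c(2200, 2200), seed = 23), raster = FALSE)
  edges <- c(0, 2, 4, 8, 16, 32, 64, 200)
  d <- build_size_distribution(np$truth, edges)
  cdf <- function(x) sum(mix$weight * plnorm(x, mix$meanlog, mix$sdlog))
  for (b in seq_len(length(edges) - 1)) {
    p <- cdf(edges[b + 1]) - cdf(edges[b])
    expect_lt(abs(d$counts[b] - 1000 * p),
              3 * sqrt(1000 * p * (1 - p)) + 1)
  }
})

section_tables <- function(n_sections, shift = 1, seed = 1) {
  lapply(seq_len(n_sections), function(s) {
    np <- generate_nerve_phantom(nerve_phantom_spec(
      n_axons = 150, image_size_px = c(800, 800),
      calibre_mixture = list(meanlog = log(4) + log(shift), sdlog = 0.5,
                             weight = 1),
      seed = seed * 100 + s), raster = FALSE)
    cbind(np$truth, section = s)
  })
}

test_that("identical groups show no group effect", {
  edges <- seq(0, 30, by = 3)
  mk <- function(tabs, g) build_size_distribution(
    do.call(rbind, tabs), edges, group = g, section = "section")
  tabs <- section_tables(4, shift = 1, seed = 3)
  cmp <- compare_distributions(list(mk(tabs, "a"), mk(tabs, "b")))
  pg <- cmp$anova$table$p[cmp$anova$table$term == "group"]
  expect_gt(pg, 0.5)
})

test_that("a calibre shift between groups is detected reliably", {
  edges <- seq(0, 30, by = 3)
  hits <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    g1 <- build_size_distribution(
      do.call(rbind, section_tables(6, shift = 1, seed = r)),
      edges, group = "wt", section = "section")
    g2 <- build_size_distribution(
      do.call(rbind, section_tables(6, shift = 1.6, seed = 50 + r)),
      edges, group = "treated", section = "section")
    cmp <- compare_distributions(list(g1, g2))
    tab <- cmp$anova$table
    p_int <- tab$p[grepl(":", tab$term)]
    # a pure shift moves counts between bins: it appears in the
    # group x bin interaction and in per-bin comparisons
    if ((length(p_int) && p_int <= 0.05) || any(cmp$per_bin$significant))
      hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("single-section groups are rejected", {
  edges <- seq(0, 30, by = 3)
  one <- build_size_distribution(
    do.call(rbind, section_tables(1, seed = 5)), edges,
    group = "a", section = "section")
  expect_error(compare_distributions(list(one, one)), ">= 2 sections")
})
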