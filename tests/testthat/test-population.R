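# Population statistics: expansion ratio, classification, mixtures, halo
# calling.

test_that("expansion ratio identity, constants and linear scaling", {
  set.seed(2)
  w <- rlnorm(80, log(0.8), 0.1)
  p <- width_population(w, rep(1:5, each = 16))
  expect_identical(expansion_ratio(p, p, n_boot = 50)$ratio, 1)
  pre <- width_population(rep(0.8, 50), rep(1:5, each = 10))
  post <- width_population(rep(1.76, 50), rep(1:5, each = 10))
  er <- expansion_ratio(pre, post, n_boot = 200, seed = 3)
  expect_equal(er$ratio, 2.2)
  expect_equal(er$sem, 0)
  expect_equal(er$n_pre, 50L)
  # multiplying all post widths by c multiplies the ratio by c
  post3 <- width_population(post$widths_um * 3, post$image_ids)
  expect_equal(expansion_ratio(pre, post3, n_boot = 10)$ratio, 3 * 2.2)
})

test_that("expansion ratio converges to the generating factor at large n", {
  set.seed(11)
  pre <- width_population(rnorm(500, 0.8, 0.05), rep(1:5, each = 100))
  post <- width_population(rnorm(500, 3.2, 0.2), rep(1:5, each = 100))
  er <- expansion_ratio(pre, post, n_boot = 1000, seed = 1)
  expect_equal(er$ratio, 4.0, tolerance = 0.02)
  expect_gt(er$sem, 0)
  # the cluster bootstrap SEM is on the scale of the analytic ratio SE
  se_analytic <- 4 * sqrt((0.05 / 0.8)^2 + (0.2 / 3.2)^2) / sqrt(500)
  expect_equal(er$sem, se_analytic, tolerance = 0.5)
})

test_that("expansion ratio edge cases", {
  p <- width_population(rep(1, 30))
  expect_error(expansion_ratio(width_population(numeric(0)), p), "nonempty")
  expect_warning(expansion_ratio(p, p, n_boot = 20), "single image")
  expect_error(width_population(c(1, -2)), "positive")
})

test_that("reference fitting: estimator consistency and sd floor", {
  set.seed(4)
  ref <- fit_reference(width_population(rnorm(500, 2.0, 0.1)), "sp")
  expect_lt(abs(ref$mean_um - 2.0), 0.02)
  expect_lt(abs(ref$sd_um - 0.1), 0.02)
  flat <- fit_reference(width_population(rep(1.5, 30)), "flat")
  expect_equal(flat$sd_um, 0.05) # half-pixel floor
  expect_error(fit_reference(width_population(rep(1, 5)), "few"), "at least 20")
  a <- fit_reference(width_population(rnorm(100, 1, 0.05)), "a")
  b <- fit_reference(width_population(rnorm(100, 3, 0.05)), "b")
  expect_gt(b$mean_um - a$mean_um, 1.5)
})

make_ref <- function(sp, mean, sd, prior = NA_real_) {
  structure(list(species = sp, mean_um = mean, sd_um = sd, prior = prior,
                 n = 100L), class = "reference_model")
}

test_that("classification against references", {
  one <- classify_widths(width_population(runif(50, 0.5, 3)),
                         make_ref("only", 1, 0.1))
  expect_true(all(one$assignments == "only"))
  expect_equal(one$composition$fraction, 1)

  refs <- list(make_ref("small", 1.0, 0.08), make_ref("large", 2.2, 0.15))
  set.seed(9)
  w <- c(rnorm(300, 1.0, 0.08), rnorm(300, 2.2, 0.15))
  res <- classify_widths(width_population(w), refs)
  truth <- rep(c("small", "large"), each = 300)
  expect_gte(mean(res$assignments == truth), 0.99)
  expect_equal(sum(res$composition$count), 600L)
  expect_equal(sum(res$composition$fraction), 1)
  # permuting the reference list leaves assignments unchanged
  res2 <- classify_widths(width_population(w), rev(refs))
  expect_identical(res2$assignments, res$assignments)
  expect_error(classify_widths(width_population(w),
                               list(make_ref("a", 1, 0.1),
                                    make_ref("b", 1, 0.2))), "distinct")
})

test_that("three-species mixture at 1:2:3 is recovered within 4 points", {
  refs <- list(make_ref("a", 1.0, 0.08), make_ref("b", 1.8, 0.12),
               make_ref("c", 3.2, 0.2))
  set.seed(21)
  w <- c(rnorm(100, 1.0, 0.08), rnorm(200, 1.8, 0.12), rnorm(300, 3.2, 0.2))
  comp <- classify_widths(width_population(w), refs)$composition
  expect_equal(comp$fraction, c(1, 2, 3) / 6, tolerance = 0.04 * 6 / 3)
  expect_true(all(abs(comp$fraction - c(1, 2, 3) / 6) <= 0.04))
})

test_that("misclassification stays within the two-normal Bayes bound", {
  # closed-form Bayes error of two equal-prior normals
  bayes_error <- function(m1, s1, m2, s2) {
    f <- function(x) 0.5 * pmin(dnorm(x, m1, s1), dnorm(x, m2, s2)) * 2
    integrate(function(x) pmin(0.5 * dnorm(x, m1, s1), 0.5 * dnorm(x, m2, s2)),
              -Inf, Inf)$value * 2
  }
  set.seed(33)
  for (i in 1:5) {
    m1 <- runif(1, 0.8, 1.2); s1 <- runif(1, 0.05, 0.12)
    gap <- 6 * max(s1, 0.1)
    m2 <- m1 + gap; s2 <- 0.1
    refs <- list(make_ref("a", m1, s1), make_ref("b", m2, s2))
    w <- c(rnorm(1000, m1, s1), rnorm(1000, m2, s2))
    res <- classify_widths(width_population(w), refs)
    err <- mean(res$assignments != rep(c("a", "b"), each = 1000))
    expect_lte(err, bayes_error(m1, s1, m2, s2) + 0.01)
  }
})

test_that("EM mixture fitting recovers well-separated components", {
  set.seed(5)
  w <- width_population(c(rnorm(500, 1.0, 0.05), rnorm(500, 4.0, 0.2)))
  fit <- fit_mixture(w, 2, seed = 1)
  expect_equal(fit[[1]]$mean_um, 1.0, tolerance = 0.05)
  expect_equal(fit[[2]]$mean_um, 4.0, tolerance = 0.1)
  expect_equal(fit[[1]]$prior, 0.5, tolerance = 0.05)
  expect_false(attr(fit, "unresolved"))
  expect_true(attr(fit, "converged"))
  # deterministic given the seed
  fit2 <- fit_mixture(w, 2, seed = 1)
  expect_identical(fit[[1]]$mean_um, fit2[[1]]$mean_um)
})

test_that("EM diagnostics: k = 1 and unimodal k = 2", {
  set.seed(6)
  x <- rnorm(200, 2, 0.3)
  w <- width_population(abs(x) + 0.01)
  one <- fit_mixture(w, 1)
  expect_equal(one[[1]]$mean_um, mean(w$widths_um))
  two <- suppressWarnings(fit_mixture(w, 2, seed = 2))
  expect_true(attr(two, "unresolved"))
  expect_error(fit_mixture(width_population(rep(1, 15)), 2), "10 \\* k")
})

test_that("halo detection on rendered two-channel scenes", {
  spec <- clean_scene_spec(n = 10L, width = 0.8, width_sd = 0.05,
                           len = 2.5, len_sd = 0.2, shape = c(600L, 600L),
                           sep = 7)
  spec$background_level <- 0.02
  spec$psf_sigma_um <- 0.1
  spec$noise <- list(shot_scale = 200, read_sd = 0.01)

  coloc <- render_halo_scene(spec, halo_fraction = 0, seed = 14)
  labs <- segment_cells(coloc$cyto_image)
  expect_equal(labs$n, 10L)
  calls <- detect_halo(labs, coloc$dna_image)
  expect_equal(nrow(calls), 10L)
  expect_false(any(calls$expanded))
  expect_equal(calls$ratio, rep(1, 10), tolerance = 0.15)

  halos <- render_halo_scene(spec, halo_fraction = 1, halo_factor = 4,
                             seed = 14)
  calls_h <- detect_halo(segment_cells(halos$cyto_image), halos$dna_image)
  expect_true(all(calls_h$expanded))
  expect_equal(mean(calls_h$ratio), 4, tolerance = 0.15)
  expect_error(detect_halo(labs, coloc$dna_image, cutoff = 0.9), "cutoff")
})

test_that("halo fraction across replicates", {
  mk <- function(f, n = 10) data.frame(expanded = rep(c(TRUE, FALSE),
                                                      c(f * n, n - f * n)))
  same <- halo_fraction(list(mk(0.3), mk(0.3), mk(0.3)))
  expect_equal(same$fraction, 0.3)
  expect_equal(same$sem, 0)
  spread <- halo_fraction(list(mk(0.2), mk(0.3), mk(0.4)))
  expect_equal(spread$fraction, 0.3)
  expect_equal(spread$sem, 0.1 / sqrt(3))
  expect_message(with_empty <- halo_fraction(list(mk(0.2), mk(0)[0, , drop = FALSE])),
                 "excluded")
  expect_equal(with_empty$n_replicates, 1L)
  expect_error(halo_fraction(list(data.frame())), "empty")
})

test_that("fixed-threshold two-population split", {
  set.seed(8)
  # in vivo style: unexpanded ~0.8 um vs ~2x-expanded ~1.65 um
  w <- width_population(c(rnorm(150, 0.8, 0.06), rnorm(100, 1.65, 0.1)))
  res <- classify_by_threshold(w, 1.2, c("L. plantarum", "E. coli"))
  expect_equal(res$composition$count, c(150L, 100L))
  expect_equal(sum(res$composition$fraction), 1)
  # agrees with posterior classification when populations are separated
  refs <- list(make_ref("L. plantarum", 0.8, 0.06),
               make_ref("E. coli", 1.65, 0.1))
  post <- classify_widths(w, refs)
  expect_gte(mean(post$assignments == res$assignments), 0.99)
  expect_error(classify_by_threshold(w, -1), "positive")
})
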