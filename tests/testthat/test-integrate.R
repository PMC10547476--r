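test_that("Z-scores use the sample SD and preserve missingness", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- c(rnorm(20), NA)
  z <- zscore(x)
  expect_true(is.na(z[21]))
  expect_lt(abs(mean(z, na.rm = TRUE)), 1e-12)
  expect_lt(abs(sd(z, na.rm = TRUE) - 1), 1e-12)
  expect_warning(z0 <- zscore(c(5, 5, 5)), "constant")
  expect_true(all(is.na(z0)))
  expect_error(zscore(c(1, NA, NA)), "non-missing")
})

test_that("normal scores fix normal-quantile input and keep the first two moments", {
  n <- 25
  x <- qnorm((sample(n) - 0.5) / n)
  ns <- normal_scores(x)
  expect_equal(ns, x, tolerance = 1e-9)
  set.seed(2)
  y <- rexp(40)
  ny <- normal_scores(y)
  expect_equal(mean(ny), mean(y), tolerance = 1e-12)
  expect_equal(var(ny), var(y), tolerance = 1e-12)
  expect_equal(order(ny), order(y))
  expect_equal(order(normal_scores(exp(y))), order(normal_scores(y)))
  yna <- c(y, NA)
  expect_true(is.na(normal_scores(yna)[41]))
})

test_that("the CORREL-form Pearson matches its defining cases and base R", {
  set.seed(3)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(as.numeric(pearson(x, x)), 1)
  expect_equal(as.numeric(pearson(x, -x)), -1)
  expect_equal(as.numeric(pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))), 0.6)
  # independent cross-check against the stock implementation
  expect_equal(as.numeric(pearson(x, y)), cor(x, y), tolerance = 1e-12)
  xm <- replace(x, 1:5, NA)
  expect_equal(as.numeric(pearson(xm, y)),
               cor(xm, y, use = "pairwise.complete.obs"), tolerance = 1e-12)
  expect_equal(attr(pearson(xm, y), "n_used"), 25L)
  # affine invariance and sign flip
  expect_equal(as.numeric(pearson(2 * x + 7, y)), as.numeric(pearson(x, y)))
  expect_equal(as.numeric(pearson(x, -y)), -as.numeric(pearson(x, y)))
  # insufficient pairs
  r <- pearson(c(1, NA, NA, 4), c(NA, 2, 3, NA))
  expect_true(is.na(r))
  expect_equal(attr(r, "n_used"), 0L)
})

test_that("correlation on Z-scored columns equals correlation on raw columns", {
  set.seed(4)
  x <- rnorm(15); y <- 3 * rnorm(15) + 2
  expect_equal(as.numeric(pearson(zscore(x), zscore(y))),
               as.numeric(pearson(x, y)), tolerance = 1e-12)
})

test_that("correlate_matrix recovers planted pairs and aligns on keys", {
  tab <- focus_param_table(seed = 5)
  focus <- default_focus_params()
  pm <- make_protein_matrix(tab, n_proteins = 4,
                            planted = data.frame(protein = "P1",
                                                 parameter = focus[1],
                                                 target_r = 1),
                            noise_sd = 0, seed = 6)
  res <- correlate_matrix(tab, pm, align = "animal")
  r11 <- res$r[res$parameter == focus[1] & res$protein == "P1"]
  expect_equal(r11, 1, tolerance = 1e-12)
  expect_equal(nrow(res), length(focus) * 4)
  # consistent row permutation leaves every r unchanged
  perm <- sample(nrow(pm))
  res_p <- correlate_matrix(tab, pm[perm, ], align = "animal")
  m <- merge(res, res_p, by = c("parameter", "protein"))
  expect_equal(m$r.x, m$r.y, tolerance = 1e-12)
})

test_that("null correlations have the moments of the null Pearson law", {
  tab <- focus_param_table(seed = 7)
  pm <- make_protein_matrix(tab, n_proteins = 100, planted = NULL,
                            noise_sd = 1, seed = 8)
  res <- correlate_matrix(tab, pm, align = "animal")
  expect_lt(abs(mean(res$r)), 0.03)
  expect_lt(abs(sd(res$r) - 1 / sqrt(15)) / (1 / sqrt(15)), 0.10)
})

test_that("group alignment is used when the animals differ", {
  tab <- focus_param_table(seed = 9)
  pm <- make_protein_matrix(tab, n_proteins = 5, planted = NULL, seed = 10)
  pm$animal <- paste0("other_", pm$animal)  # disjoint animal ids
  expect_error(res <- correlate_matrix(tab, pm, align = "auto"), NA)
  # strain x sex means leave 16 groups of one animal each here
  expect_true(all(res$n_used == 16))
  sub <- correlate_matrix(tab, pm, scope = c("S1", "S2", "S3", "S4"))
  expect_true(all(sub$n_used == 8))
})

test_that("too few points in scope yields missing correlations, never numbers", {
  tab <- focus_param_table(seed = 12)
  pm <- make_protein_matrix(tab, n_proteins = 3, planted = NULL, seed = 13)
  res <- correlate_matrix(tab, pm, align = "animal", scope = "S1")  # 2 animals
  expect_true(all(is.na(res$r)))
  expect_true(all(res$n_used == 2))
})

test_that("candidate flagging applies the |r| >= 0.5, >= 3 parameter rule", {
  res <- data.frame(
    parameter = rep(c("a", "b", "c", "d"), times = 2),
    protein = rep(c("hit", "miss"), each = 4),
    r = c(0.5, -0.6, 0.7, 0.1, 0.49, -0.49, 0.2, 0.3),
    n_used = 16L, stringsAsFactors = FALSE)
  class(res) <- c("correlation_result", "data.frame")
  fl <- flag_candidates(res, focus = c("a", "b", "c"), threshold = 0.5,
                        min_params = 3)
  expect_equal(fl$flagged[fl$protein_id == "hit"], TRUE)
  expect_equal(fl$n_high[fl$protein_id == "hit"], 3L)
  expect_equal(fl$flagged[fl$protein_id == "miss"], FALSE)
  expect_error(flag_candidates(res, focus = "nope"), "unknown focus")
  # monotone: lowering the threshold never unflags
  fl_lo <- flag_candidates(res, focus = c("a", "b", "c"), threshold = 0.3,
                           min_params = 3)
  expect_true(all(fl_lo$n_high >= fl$n_high))
  expect_true(all(fl_lo$flagged | !fl$flagged))
})

test_that("planted regulators are flagged with few false positives", {
  tab <- focus_param_table(seed = 1)
  focus <- default_focus_params()
  # regulators planted on the (mutually correlated) silent-duration trio;
  # planting |r| = 0.9 on three mutually independent parameters is infeasible
  # (the squared correlations to independent targets cannot exceed 1)
  planted <- expand.grid(protein = paste0("REG", 1:5),
                         parameter = silent_focus_params(),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # anticorrelated regulators (REG2, REG4) keep one sign across the trio
  planted$target_r <- ifelse(planted$protein %in% c("REG2", "REG4"), -0.9, 0.9)
  pm <- make_protein_matrix(tab, n_proteins = 100, planted = planted,
                            noise_sd = 1, seed = 1)
  res <- correlate_matrix(tab, pm, align = "animal")
  fl <- flag_candidates(res, focus = focus)
  expect_true(all(fl$flagged[grepl("^REG", fl$protein_id)]))
  expect_lte(sum(fl$flagged[grepl("^null", fl$protein_id)]), 2L)
})

test_that("term effects separate exact strain structure from noise", {
  strains <- rep(sprintf("S%d", 1:4), each = 4)
  sexes <- rep(c("F", "M"), times = 8)
  means <- c(S1 = 0, S2 = 2, S3 = 4, S4 = 6)
  te <- suppressWarnings(term_effects(means[strains], strains, sexes))  # exact fit
  expect_lt(te$p_value[te$term == "strain"], 1e-10)
  expect_equal(te$effect_sd_ratio[te$term == "sex"], 0, tolerance = 1e-6)
  # permuting strain labels destroys the effect
  set.seed(14)
  ps <- vapply(1:20, function(i) {
    perm <- sample(strains)
    term_effects(means[strains], perm, sexes)$p_value[1]
  }, numeric(1))
  expect_gt(median(ps), 0.1)
})

test_that("null traits give approximately uniform strain p-values", {
  strains <- rep(sprintf("S%d", 1:4), each = 4)
  sexes <- rep(c("F", "M"), times = 8)
  set.seed(15)
  ps <- vapply(1:200, function(i) {
    term_effects(rnorm(16), strains, sexes)$p_value[1]
  }, numeric(1))
  frac <- mean(ps < 0.1)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.16)
})

test_that("a single-sex design reports the strain term and leaves sex missing", {
  strains <- rep(c("A", "B"), each = 4)
  te <- term_effects(rnorm(8), strains, rep("F", 8))
  expect_false(is.na(te$p_value[te$term == "strain"]))
  expect_true(is.na(te$p_value[te$term == "sex"]))
})

test_that("the composite signal term captures strain-involving variation", {
  strains <- rep(sprintf("S%d", 1:4), each = 4)
  sexes <- rep(c("F", "M"), times = 8)
  set.seed(16)
  y <- c(S1 = 0, S2 = 1, S3 = 2, S4 = 3)[strains] + rnorm(16, sd = 0.1)
  te <- term_effects(y, strains, sexes)
  expect_lt(te$p_value[te$term == "signal"], 0.001)
  tab <- data.frame(strain = strains, sex = sexes, trait1 = y,
                    stringsAsFactors = FALSE)
  tt <- term_effects_table(tab)
  expect_equal(nrow(tt), 4L)
  expect_equal(unique(tt$trait_id), "trait1")
})
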