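# Allele-score construction and harmonization, calibration, the two MR
# estimators and their identities, sensitivity diagnostics, trait screen,
# and the cumulative score-trait regression.

test_that("equal weights make the score proportional to the allele count", {
  set.seed(1)
  g <- matrix(rbinom(300, 2, 0.4), 100, 3,
              dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  w <- score_definition("t", data.frame(
    snp = c("rs1", "rs2", "rs3"), ea = "A", oa = "G", weight = 0.2))
  expect_equal(build_score(w, g), 0.2 * rowSums(g),
               ignore_attr = TRUE)
})

test_that("allele-swapped storage leaves the score unchanged", {
  set.seed(2)
  g <- matrix(rbinom(400, 2, 0.3), 200, 2,
              dimnames = list(NULL, c("rs1", "rs2")))
  w <- score_definition("t", data.frame(
    snp = c("rs1", "rs2"), ea = c("A", "C"), oa = c("G", "T"),
    weight = c(0.3, -0.1)))
  aligned <- data.frame(snp = c("rs1", "rs2"), ea = c("A", "C"),
                        oa = c("G", "T"))
  swapped <- data.frame(snp = c("rs1", "rs2"), ea = c("G", "T"),
                        oa = c("A", "C"))
  s1 <- build_score(w, g, aligned)
  s2 <- build_score(w, 2 - g, swapped)    # dosages count the other allele
  expect_equal(s1, s2)
})

test_that("strand-complement storage is resolved; mismatches are dropped", {
  set.seed(3)
  g <- matrix(rbinom(600, 2, 0.3), 200, 3,
              dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  w <- score_definition("t", data.frame(
    snp = c("rs1", "rs2", "rs3"), ea = c("A", "C", "A"),
    oa = c("G", "T", "G"), weight = c(0.2, 0.1, 0.4)))
  # rs1 on the other strand (T/C), rs2 aligned, rs3 alleles unrelated
  alle <- data.frame(snp = c("rs1", "rs2", "rs3"), ea = c("T", "C", "C"),
                     oa = c("C", "T", "G"))
  expect_warning(s <- build_score(w, g, alle), "unresolvable")
  expect_equal(attr(s, "n_snps_used"), 2L)
  expect_equal(s, drop(g[, 1:2] %*% c(0.2, 0.1)), ignore_attr = TRUE)
})

test_that("palindromic SNPs use frequency when informative, else drop", {
  set.seed(4)
  g <- matrix(rbinom(1000, 2, 0.8), 500, 2,
              dimnames = list(NULL, c("rs1", "rs2")))
  alle <- data.frame(snp = c("rs1", "rs2"), ea = c("A", "A"),
                     oa = c("T", "T"))
  # informative frequency (0.8 vs 0.5): kept, aligned by matching side
  w1 <- score_definition("t", data.frame(
    snp = c("rs1", "rs2"), ea = "A", oa = "T", weight = 0.2,
    eaf = c(0.8, 0.8)))
  s <- build_score(w1, g, alle)
  expect_equal(attr(s, "n_snps_used"), 2L)
  expect_equal(s, 0.2 * rowSums(g), ignore_attr = TRUE)
  # opposite frequency side implies the flipped orientation
  w2 <- score_definition("t", data.frame(
    snp = "rs1", ea = "A", oa = "T", weight = 0.2, eaf = 0.2))
  s2 <- build_score(w2, g[, 1, drop = FALSE], alle[1, ])
  expect_equal(s2, 0.2 * (2 - g[, 1]), ignore_attr = TRUE)
  # uninformative frequency: dropped with a warning
  gmid <- matrix(rbinom(1000, 2, 0.5), 500, 2,
                 dimnames = list(NULL, c("rs1", "rs2")))
  expect_warning(
    expect_error(build_score(w1, gmid, alle), "no SNPs"),
    "palindromic")
})

test_that("missing dosages are mean-imputed", {
  g <- matrix(c(0, 1, 2, NA, 1, 1, 2, 0), 4, 2,
              dimnames = list(NULL, c("rs1", "rs2")))
  w <- score_definition("t", data.frame(snp = c("rs1", "rs2"),
                                        ea = "A", oa = "G", weight = 1))
  s <- build_score(w, g)
  expect_equal(s[4], mean(c(0, 1, 2)) + 0, ignore_attr = TRUE)
})

test_that("score calibration recovers exposure units", {
  fx <- make_mr_fixture(n = 20000, seed = 101)
  s <- build_score(fx$weights, fx$cohort$genotypes)
  cal <- calibrate_score(s, fx$cohort$exposure)
  # regression slope of exposure on raw score is 1/calibration by definition
  expect_equal(unname(coef(lm(fx$cohort$exposure ~ s))[2]), c(cal),
               ignore_attr = TRUE)
  # exposure identical to the raw score: calibration is exactly 1
  expect_equal(c(suppressWarnings(calibrate_score(s, s))), 1,
               tolerance = 1e-12)
  expect_error(calibrate_score(rep(1, 10), rnorm(10)), "no variance")
  expect_error(calibrate_score(1:10, -(1:10)), "positive")
})

test_that("single-SNP estimate reduces to the Wald ratio", {
  set.seed(6)
  n <- 30000
  g <- rbinom(n, 2, 0.4)
  x <- 0.25 * g + rnorm(n)
  x <- (x - mean(x)) / sd(x)
  y <- rbinom(n, 1, plogis(-2.5 + 0.5 * x))
  b_gx <- unname(coef(lm(x ~ g))[2])
  b_gy <- unname(coef(glm(y ~ g, family = binomial()))[2])
  w <- score_definition("t", data.frame(snp = "rs1", ea = "A", oa = "G",
                                        weight = b_gx))
  s <- build_score(w, matrix(g, ncol = 1, dimnames = list(NULL, "rs1")))
  est <- mr_individual(s, y, calibration = calibrate_score(s, x))
  expect_equal(est$beta, b_gy / b_gx, tolerance = 1e-8)
})

test_that("mr_summary equals IVW over per-SNP Wald ratios exactly", {
  set.seed(7)
  for (i in 1:5) {
    m <- sample(3:12, 1)
    stats_tab <- data.frame(
      snp = paste0("rs", 1:m), ea = "A", oa = "G",
      beta = rnorm(m, 0.1, 0.2), se = runif(m, 0.02, 0.2),
      stringsAsFactors = FALSE)
    w <- runif(m, 0.02, 0.3) * sample(c(-1, 1), m, replace = TRUE)
    sd_def <- score_definition("t", data.frame(
      snp = stats_tab$snp, ea = "A", oa = "G", weight = w))
    est <- mr_summary(stats_tab, sd_def)
    ratios <- stats_tab$beta / w
    ratio_se <- stats_tab$se / abs(w)
    ivw <- ivw_meta(data.frame(beta = ratios, se = ratio_se))
    expect_equal(est$beta, ivw$beta, tolerance = 1e-10)
    expect_equal(est$se, ivw$se, tolerance = 1e-10)
  }
})

test_that("identical Wald ratios combine to exactly that ratio", {
  m <- 6
  w <- runif(m, 0.05, 0.2)
  r <- 0.42
  stats_tab <- data.frame(snp = paste0("rs", 1:m), ea = "A", oa = "G",
                          beta = r * w, se = runif(m, 0.02, 0.1))
  sd_def <- score_definition("t", data.frame(snp = stats_tab$snp, ea = "A",
                                             oa = "G", weight = w))
  expect_equal(mr_summary(stats_tab, sd_def)$beta, r, tolerance = 1e-12)
})

test_that("estimates are invariant to allele relabelling with sign flip", {
  set.seed(9)
  m <- 8
  stats_tab <- data.frame(snp = paste0("rs", 1:m), ea = "A", oa = "G",
                          eaf = runif(m, 0.2, 0.8),
                          beta = rnorm(m, 0.1, 0.2), se = runif(m, 0.02, 0.2))
  sd_def <- score_definition("t", data.frame(snp = stats_tab$snp, ea = "A",
                                             oa = "G", weight = runif(m, 0.05, 0.3)))
  flipped <- transform(stats_tab, ea = "G", oa = "A", beta = -beta,
                       eaf = 1 - eaf)
  e1 <- mr_summary(stats_tab, sd_def)
  e2 <- mr_summary(flipped, sd_def)
  expect_equal(e1$beta, e2$beta, tolerance = 1e-12)
  expect_equal(e1$se, e2$se, tolerance = 1e-12)
})

test_that("individual-level and summary-level estimators agree on one cohort", {
  fx <- make_mr_fixture(n = 20000, causal_log_or = log(1.6), seed = 55)
  coh <- fx$cohort
  st <- logistic_assoc(coh$genotypes, coh$outcome,
                       effect_allele = rep("A", 15), other_allele = rep("G", 15))
  est_sum <- mr_summary(st, fx$weights)
  s <- build_score(fx$weights, coh$genotypes)
  est_ind <- mr_individual(s, coh$outcome,
                           calibration = calibrate_score(s, coh$exposure))
  expect_lt(abs(est_sum$beta - est_ind$beta), est_sum$se)
})

test_that("per-SNP sensitivity flags planted pleiotropy and not null SNPs", {
  fx <- make_mr_fixture(n = 50000, causal_log_or = log(1.5), seed = 77)
  coh <- fx$cohort
  st <- logistic_assoc(coh$genotypes, coh$outcome)
  st$ea <- "A"; st$oa <- "G"
  sens <- per_snp_sensitivity(st, fx$weights)
  expect_equal(nrow(sens), 15)
  expect_equal(sens$precision, 1 / sens$se)
  expect_lte(sum(sens$flagged), 1)   # homogeneous effects: ~no outliers

  # plant a direct (pleiotropic) outcome effect 5x the mediated one on SNP 1
  st2 <- st
  mediated <- fx$weights$snps$weight[1] * log(1.5)
  st2$beta[1] <- st2$beta[1] + 5 * mediated
  sens2 <- per_snp_sensitivity(st2, fx$weights)
  expect_true(sens2$flagged[1])

  # duplicated SNPs give identical sensitivity rows
  w2 <- score_definition("t", data.frame(
    snp = c("snp1", "snp2"), ea = "A", oa = "G",
    weight = rep(fx$weights$snps$weight[1], 2)))
  st3 <- st[1:2, ]; st3$beta[2] <- st3$beta[1]; st3$se[2] <- st3$se[1]
  sens3 <- per_snp_sensitivity(st3, w2)
  expect_equal(sens3$wald_ratio[1], sens3$wald_ratio[2])
  expect_equal(sens3$se[1], sens3$se[2])
})

test_that("trait screen applies the Bonferroni threshold exactly", {
  scr <- trait_screen(c(0.003, 0.004, 0.0001), n_traits = 15)
  expect_equal(scr$threshold, 0.05 / 15)
  expect_equal(scr$threshold, 0.003333, tolerance = 1e-3)
  expect_identical(scr$significant, c(TRUE, FALSE, TRUE))
  expect_equal(trait_screen(0.04, n_traits = 1)$threshold, 0.05)
  expect_error(trait_screen(0.1, 0), "n_traits")
})

test_that("cumulative score regression on a log trait behaves", {
  set.seed(10)
  g <- matrix(rbinom(3000, 2, 0.4), 1000, 3,
              dimnames = list(NULL, paste0("rs", 1:3)))
  w <- score_definition("t", data.frame(snp = paste0("rs", 1:3), ea = "A",
                                        oa = "G", weight = c(0.2, 0.1, 0.3)))
  s <- build_score(w, g)
  # trait = exp(score) exactly: slope 1, p ~ 0
  res <- suppressWarnings(cumulative_score_trait(w, g, exp(s)))
  expect_equal(res$slope, 1, tolerance = 1e-10)
  expect_lt(res$p, 1e-12)
  expect_error(cumulative_score_trait(w, g, c(-1, runif(999))), "positive")

  # null: p-values uniform across replicates
  pvals <- replicate(200, {
    tr <- exp(rnorm(1000))
    cumulative_score_trait(w, g, tr)$p
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("mr_individual rejects degenerate scores and missing classes", {
  expect_error(mr_individual(rep(1, 50), rbinom(50, 1, 0.5)), "no variance")
  expect_error(mr_individual(rnorm(50), rep(1, 50)), "both")
})
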