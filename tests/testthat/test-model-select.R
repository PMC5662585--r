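fast <- hslmm_control(n_starts = 1)

test_that("structure screening recovers compound symmetry", {
  hits <- vapply(1:20, function(s) {
    d <- sim_repeated(150, 4, cs_cov(4, 1, 0.45), seed = 500 + s)
    sel <- select_structure(y ~ x + grp, d, subject = "subj",
                            order = "ord",
                            candidates = c("cs", "ar1", "un"),
                            control = fast)
    sel$chosen == "cs"
  }, logical(1))
  expect_gte(sum(hits), 16)
})

test_that("nested LRT statistics are non-negative with correct df", {
  d <- sim_repeated(60, 4, ar1_cov(4, 1, 0.5), seed = 21)
  fits <- lapply(c(iid = "iid", ar1 = "ar1", toep = "toep", un = "un"),
                 function(s) hslmm(y ~ x, d, subject = "subj",
                                   order = "ord", structure = s,
                                   control = fast))
  pairs <- list(c("iid", "ar1"), c("ar1", "toep"), c("ar1", "un"),
                c("toep", "un"))
  for (p in pairs) {
    stat <- fits[[p[1]]]$m2ll - fits[[p[2]]]$m2ll
    expect_gte(stat, -1e-6)
    expect_gt(fits[[p[2]]]$q, fits[[p[1]]]$q)
  }
})

test_that("the null LRT p-value is approximately uniform", {
  ## AR1 truth, AR1 vs UN comparison; chi-square reference with
  ## df = difference in covariance parameters
  ps <- vapply(1:100, function(s) {
    d <- sim_repeated(100, 3, ar1_cov(3, 1, 0.4), seed = 900 + s,
                      groups = 1)
    fa <- hslmm(y ~ x, d, subject = "subj", order = "ord",
                structure = "ar1", control = fast)
    fu <- hslmm(y ~ x, d, subject = "subj", order = "ord",
                structure = "un", control = fast)
    pchisq(max(fa$m2ll - fu$m2ll, 0), df = fu$q - fa$q,
           lower.tail = FALSE)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("interaction pruning keeps real effects and drops noise", {
  sim_prune <- function(seed, effect) {
    set.seed(seed)
    n <- 60
    d <- expand.grid(subj = sprintf("s%03d", 1:n), ord = 1:3)
    d$a <- factor(rep(rep(c("a1", "a2"), length.out = n), 3))
    d$b <- factor(rep(rep(c("b1", "b2"), each = n / 2), 3))
    d$y <- 0.5 * (d$a == "a2") + 0.3 * (d$b == "b2") +
      effect * (d$a == "a2" & d$b == "b2") +
      rep(rnorm(n, 0, 0.5), 3) + rnorm(3 * n, 0, 1)
    prune_interactions(y ~ a + b + a:b, d, subject = "subj",
                       order = "ord", structure = "cs", control = fast)
  }
  kept_null <- vapply(1:20, function(s)
    nrow(sim_prune(600 + s, 0)$trail) == 0, logical(1))
  expect_gte(sum(!kept_null), 14)   # interaction removed in most null sims
  kept_eff <- vapply(1:20, function(s)
    nrow(sim_prune(700 + s, 1.5)$trail) == 0, logical(1))
  expect_gte(sum(kept_eff), 19)     # strong interaction retained
  ## boundary: alpha = 1 strips every interaction before fitting
  pr <- sim_prune(801, 1.5)
  pr1 <- prune_interactions(y ~ a + b + a:b,
                            sim_prune(801, 1.5)$fit$model_data,
                            subject = "subj", order = "ord",
                            structure = "cs", alpha = 1, control = fast)
  expect_equal(pr1$trail$dropped, "a:b")
  expect_false(any(grepl(":", attr(terms(pr1$formula), "term.labels"))))
})

test_that("LS means reduce to sample and cell means where they should", {
  set.seed(31)
  n <- 24
  d <- expand.grid(subj = sprintf("s%02d", 1:n), ord = 1:2)
  d$g <- factor(rep(rep(c("u", "v", "w"), each = n / 3), 2))
  d$y <- rnorm(2 * n, 5, 1)
  f0 <- hslmm(y ~ 1, d, subject = "subj", order = "ord",
              structure = "iid", control = fast)
  expect_equal(unname(f0$beta), mean(d$y), tolerance = 1e-8)
  f1 <- hslmm(y ~ g, d, subject = "subj", order = "ord",
              structure = "iid", control = fast)
  lsm <- ls_means(f1, "g")
  cell <- tapply(d$y, d$g, mean)
  expect_equal(lsm$means$estimate, as.vector(cell[lsm$means$level]),
               tolerance = 1e-8)
  ## pairwise contrast equals difference of estimates
  pr <- lsm$pairs
  for (i in seq_len(nrow(pr)))
    expect_equal(pr$diff[i],
                 lsm$means$estimate[lsm$means$level == pr$level1[i]] -
                   lsm$means$estimate[lsm$means$level == pr$level2[i]],
                 tolerance = 1e-10)
})

test_that("LS means flag empty cells instead of failing", {
  set.seed(32)
  d <- expand.grid(subj = sprintf("s%02d", 1:20), ord = 1:2)
  d$g <- factor(rep(rep(c("u", "v"), each = 10), 2), c("u", "v", "w"))
  d$y <- rnorm(40)
  f <- hslmm(y ~ g, d, subject = "subj", order = "ord",
             structure = "iid", control = fast)
  expect_warning(lsm <- ls_means(f, "g"), "empty")
  expect_equal(sort(lsm$means$level), c("u", "v"))
})

test_that("noiseless cohort LS means echo the configured line means", {
  sch <- default_schedule()
  coh <- generate_cohort(noiseless_config(2), sch, seed = 51)
  ph <- derive_phenotypes(coh, sch)$phenotypes
  ph$period_idx <- as.integer(factor(ph$period))
  f <- hslmm(bwg ~ line * climate, ph, subject = "pig_id",
             order = "period_idx", structure = "iid", control = fast)
  lsm <- ls_means(f, "line:climate")
  expect_equal(lsm$means$estimate[lsm$means$level == "commercial:TN"],
               1.22, tolerance = 1e-6)
  expect_equal(lsm$means$estimate[lsm$means$level == "lowRFI:TN"],
               0.720, tolerance = 1e-6)
})
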