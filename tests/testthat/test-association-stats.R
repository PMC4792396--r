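make_frame <- function(n = 100, tissue = "SM", seed = 1, mtcn_fun = NULL) {
  set.seed(seed)
  age <- runif(n, 0, 96)
  mtcn <- if (is.null(mtcn_fun)) 10^rnorm(n, 3.3, 0.15) else mtcn_fun(age)
  data.frame(individual_id = sprintf("I%03d", 1:n), tissue = tissue,
             method = "shotgun", mtcn = mtcn, age = age,
             sex = rep(c("m", "f"), length.out = n),
             haplogroup = sample(c("H", "J", "U", "other"), n, TRUE),
             het_count = rpois(n, 3), stringsAsFactors = FALSE)
}

test_that("normality gate usually passes matched log-normal data untouched", {
  # the gate tests at alpha = 0.05, so ~1 in 20 truly log-normal cohorts
  # triggers an exclusion by design; check the expectation across seeds
  untouched <- 0
  for (s in 1:5) {
    f <- make_frame(n = 100, seed = s)
    pt <- suppressWarnings(prepare_tissue(f, "SM"))
    if (nrow(pt$exclusions) == 0 && pt$normality_ok)
      untouched <- untouched + 1
    expect_equal(pt$frame$log_mtcn, log10(pt$frame$mtcn))
  }
  expect_gte(untouched, 4)
})

test_that("normality gate removes an extreme-mtCN sample first", {
  f <- make_frame(n = 100, seed = 3)
  f$mtcn[40] <- median(f$mtcn) * 100  # planted 100-fold outlier
  pt <- prepare_tissue(f, "SM")
  expect_true("I040" %in% pt$exclusions$individual_id)
  expect_equal(pt$exclusions$reason[1], "NORMALITY")
  expect_false("I040" %in% pt$frame$individual_id)
})

test_that("normality gate stops at max_exclusions and flags the result", {
  set.seed(4)
  f <- make_frame(n = 60, seed = 4,
                  mtcn_fun = function(a) 10^runif(length(a), 1, 6))  # far from normal
  expect_warning(pt <- prepare_tissue(f, "SM", max_exclusions = 2),
                 "normality not achieved")
  expect_equal(nrow(pt$exclusions), 2)
  expect_false(pt$normality_ok)
  expect_error(prepare_tissue(make_frame(2), "SM"), "fewer than 3")
})

test_that("correlate reports r, F and p consistently (F = t^2 world)", {
  f <- make_frame(n = 50, seed = 5,
                  mtcn_fun = function(a) 10^(3 - 0.01 * a))  # exact line
  res <- correlate(f, "age")
  expect_equal(res$r, -1)
  expect_lt(res$p_raw, 1e-12)
  # against cor.test as the independent route
  f2 <- make_frame(n = 80, seed = 6)
  res2 <- correlate(f2, "age")
  ct <- cor.test(f2$age, log10(f2$mtcn))
  expect_equal(res2$r, unname(ct$estimate))
  expect_equal(res2$p_raw, ct$p.value)
  expect_equal(res2$F, unname(ct$statistic)^2)
  expect_error(correlate(transform(f2, k = 1), "k"), "constant")
})

test_that("independent predictor and response give small r at n = 1000", {
  hits <- 0
  for (s in 1:5) {
    f <- make_frame(n = 1000, seed = 100 + s)
    r <- correlate(f, "age")$r
    if (abs(r) < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 5)  # |r| ~ N(0, 1/sqrt(1000)); 0.1 is > 3 SD
})

test_that("planted age slope is detected with the generator's noise level", {
  detected <- 0
  for (s in 1:10) {
    f <- make_frame(n = 150, seed = 200 + s,
                    mtcn_fun = function(a) 10^(3.46 - 0.003 * a +
                                                 rnorm(length(a), 0, 0.15)))
    res <- correlate(f, "age")
    if (res$r < 0 && res$p_raw < 0.05) detected <- detected + 1
  }
  expect_gte(detected, 8)
})

test_that("age-window and mtCN-threshold filters restrict the tested subset", {
  f <- make_frame(n = 120, seed = 18)
  over50 <- correlate(f, "age", age_range = c(50, 96))
  expect_equal(over50$n, sum(f$age >= 50 & f$age <= 96))
  thr <- median(f$mtcn)
  high <- correlate(f, "age", mtcn_range = c(thr, Inf))
  expect_equal(high$n, sum(f$mtcn >= thr))
  # oracle on the subset
  sub <- f[f$mtcn >= thr, ]
  expect_equal(high$r, cor(sub$age, log10(sub$mtcn)))
})

test_that("group comparison: identical groups F = 0, separated groups significant", {
  f <- make_frame(n = 40, seed = 7)
  f$mtcn <- rep(1000, 40)
  res <- group_compare(f, "sex")
  expect_equal(res$F, 0)
  expect_equal(res$p_raw, 1)

  f2 <- make_frame(n = 40, seed = 8)
  f2$log_mtcn <- NULL
  # shift males by 5 SD of the log distribution
  s <- sd(log10(f2$mtcn))
  f2$mtcn[f2$sex == "m"] <- f2$mtcn[f2$sex == "m"] * 10^(5 * s)
  res2 <- group_compare(f2, "sex")
  expect_lt(res2$p_raw, 0.001)
})

test_that("haplogroup contrasts test each major group against the rest", {
  f <- make_frame(n = 120, seed = 9)
  res <- group_compare(f, "haplogroup")
  expect_setequal(res$test_id,
                  c("haplogroup_H", "haplogroup_J", "haplogroup_U"))
  expect_true(all(res$p_adj >= res$p_raw))
  # a group with < 2 members is skipped
  f2 <- f[f$haplogroup != "J" | seq_len(nrow(f)) == which(f$haplogroup == "J")[1], ]
  res2 <- group_compare(f2, "haplogroup")
  expect_false("haplogroup_J" %in% res2$test_id)
})

test_that("null sex comparison yields roughly uniform p-values", {
  ps <- vapply(1:20, function(s)
    group_compare(make_frame(n = 80, seed = 300 + s), "sex")$p_raw,
    numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the hand-derived examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.5, 7)), rep(0.5, 7))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  set.seed(10)
  for (k in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), info = paste("draw", k))
  }
})

test_that("partial regression with one predictor reproduces correlate exactly", {
  f <- make_frame(n = 70, seed = 11)
  pr <- partial_regression(f, "age")
  co <- correlate(f, "age")
  expect_equal(pr$p_partial, co$p_raw)
  expect_equal(sign(pr$estimate), sign(co$r))
})

test_that("orthogonal covariates leave the focal partial p unchanged", {
  set.seed(12)
  n <- 80
  age <- rnorm(n)
  z <- rnorm(n)
  z_orth <- residuals(lm(z ~ age))  # exactly orthogonal to age
  f <- make_frame(n = n, seed = 12)
  f$age <- age
  f$z <- z_orth
  f$mtcn <- 10^(3 + 0.2 * age + rnorm(n, 0, 0.1))
  pr <- partial_regression(f, c("age", "z"))
  simple <- correlate(f, "age")
  expect_equal(pr$p_partial[pr$predictor == "age"], simple$p_raw,
               tolerance = 1e-6)
})

test_that("collinear designs are rejected with the offending pair named", {
  f <- make_frame(n = 50, seed = 13)
  f$age2 <- 2 * f$age
  err <- tryCatch(partial_regression(f, c("age", "age2")),
                  error = function(e) conditionMessage(e))
  expect_match(err, "collinear")
  expect_match(err, "age")
  expect_match(err, "age2")
  f$k <- 5
  expect_error(partial_regression(f, c("age", "k")), "constant")
})

test_that("age-driven confounding is resolved: direct predictor beats proxy", {
  wins <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 150
    age <- runif(n, 0, 96)
    maf <- pmax(0.002 * age + rnorm(n, 0, 0.04), 0)  # proxy of age
    f <- make_frame(n = n, seed = 400 + s)
    f$age <- age
    f$maf <- maf
    f$mtcn <- 10^(3.46 - 0.004 * age + rnorm(n, 0, 0.15))  # age only
    pr <- partial_regression(f, c("age", "maf"))
    if (pr$p_partial[pr$predictor == "age"] <
          pr$p_partial[pr$predictor == "maf"]) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("jointly planted age and MAF effects are both recovered", {
  both <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    n <- 150
    age <- runif(n, 0, 96)
    maf <- pmin(pmax(0.0015 * age + rnorm(n, 0, 0.04), 0), 0.28)
    f <- make_frame(n = n, seed = 500 + s)
    f$age <- age
    f$maf <- maf
    f$mtcn <- 10^(3.46 - 0.003 * age - 1.5 * maf + rnorm(n, 0, 0.15))
    pr <- partial_regression(f, c("age", "maf"))
    if (all(pr$p_partial[pr$predictor %in% c("age", "maf")] < 0.05))
      both <- both + 1
  }
  expect_gte(both, 8)
})

test_that("site MAF tests respect the minimum-carrier rule", {
  f <- make_frame(n = 60, seed = 14)
  het <- data.frame(individual_id = sprintf("I%03d", 1:9), tissue = "SM",
                    site = 408L, maf = runif(9, 0.02, 0.2))
  expect_message(res <- site_maf_tests(f, het, min_carriers = 10),
                 ">= 10 carriers")
  expect_equal(nrow(res), 0)
  het10 <- data.frame(individual_id = sprintf("I%03d", 1:10), tissue = "SM",
                      site = 408L, maf = runif(10, 0.02, 0.2))
  res10 <- site_maf_tests(f, het10, min_carriers = 10)
  expect_equal(nrow(res10), 1)
  expect_equal(res10$predictor, "maf_408")
  expect_equal(res10$n, 60)  # non-carriers included at MAF 0
  res_c <- site_maf_tests(f, het10, min_carriers = 10, carriers_only = TRUE)
  expect_equal(res_c$n, 10)
})

test_that("no heteroplasmy means no tests, with a note", {
  f <- make_frame(n = 30, seed = 15)
  het0 <- data.frame(individual_id = character(), tissue = character(),
                     site = integer(), maf = numeric())
  expect_message(res <- site_maf_tests(f, het0), "no heteroplasmic")
  expect_equal(nrow(res), 0)
})

test_that("a planted MAF-coupled site is flagged while a decoy is not", {
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(seed = 600 + s,
                      maf_sites = data.frame(
                        site = c(408L, 9999L), tissue = "SM",
                        slope = c(0.0015, 0.0015), ceiling = c(0.282, 0.282),
                        coupling = c(-1.5, 0)))  # decoy uncoupled
    sim <- simulate_cohort(cfg)
    pt <- prepare_tissue(sim$cohort, "SM")
    res <- site_maf_tests(pt$frame, sim$heteroplasmy)
    p408 <- res$p_adj[res$predictor == "maf_408"]
    pdec <- res$p_adj[res$predictor == "maf_9999"]
    if (length(p408) && length(pdec) && p408 < 0.05 && pdec > p408)
      hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("pair and triplet predictors combine member-site MAFs among joint carriers", {
  set.seed(16)
  f <- make_frame(n = 80, seed = 16)
  ids <- f$individual_id
  het <- rbind(
    data.frame(individual_id = ids[1:40], tissue = "SM", site = 1L,
               maf = runif(40, 0.02, 0.2)),
    data.frame(individual_id = ids[21:60], tissue = "SM", site = 2L,
               maf = runif(40, 0.02, 0.2)))
  res <- site_maf_tests(f, het, min_carriers = 10, arity = 2)
  expect_equal(res$predictor, "maf_1+2")
  expect_equal(res$n, 20)  # individuals 21..40 carry both
  # oracle: correlation of the MAF sum among joint carriers
  joint <- ids[21:40]
  x <- het$maf[het$site == 1][match(joint, het$individual_id[het$site == 1])] +
    het$maf[het$site == 2][match(joint, het$individual_id[het$site == 2])]
  y <- log10(f$mtcn[match(joint, f$individual_id)])
  expect_equal(res$r, cor(x, y))
  # triplets need three qualifying sites
  expect_message(site_maf_tests(f, het, min_carriers = 10, arity = 3),
                 "no site combination")
})

test_that("tissue pair matrix recovers planted inter-tissue correlation only", {
  hits <- 0
  for (s in 1:10) {
    set.seed(700 + s)
    n <- 120
    shared <- rnorm(n)
    mk <- function(tis, loading) {
      data.frame(individual_id = sprintf("I%03d", 1:n), tissue = tis,
                 method = "shotgun",
                 mtcn = 10^(3 + loading * shared * 0.15 +
                              rnorm(n, 0, 0.15 * sqrt(1 - loading^2))),
                 stringsAsFactors = FALSE)
    }
    f <- rbind(mk("A", sqrt(0.5)), mk("B", sqrt(0.5)), mk("C", 0))
    pm <- tissue_pair_matrix(f)
    sig <- pm[!is.na(pm$p_adj) & pm$p_adj < 0.05, ]
    if (nrow(sig) == 1 && sig$tissue1 == "A" && sig$tissue2 == "B")
      hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("a tissue correlates perfectly with a copy of itself", {
  f <- make_frame(n = 30, seed = 17)
  dup <- f
  dup$tissue <- "SM2"
  pm <- tissue_pair_matrix(rbind(f, dup))
  expect_equal(pm$r, 1)
  expect_lt(pm$p_adj, 1e-10)
})

test_that("permuting individual labels destroys inter-tissue correlation", {
  fails <- 0
  for (s in 1:5) {
    set.seed(800 + s)
    f <- rbind(make_frame(n = 100, tissue = "A", seed = 800 + s),
               make_frame(n = 100, tissue = "B", seed = 900 + s),
               make_frame(n = 100, tissue = "C", seed = 1000 + s))
    pm <- tissue_pair_matrix(f)
    if (any(pm$p_adj < 0.05, na.rm = TRUE)) fails <- fails + 1
  }
  expect_lte(fails, 1)
})

test_that("the battery corrects within analysis families and stacks tidily", {
  cfg <- sim_config(seed = 19)
  sim <- simulate_cohort(cfg)
  bat <- suppressWarnings(association_battery(sim$cohort, sim$heteroplasmy))
  expect_setequal(unique(bat$results$analysis),
                  c("age", "sex", "haplogroup", "het_count", "maf"))
  expect_true(all(bat$results$p_adj >= bat$results$p_raw - 1e-12))
  for (an in c("age", "sex", "het_count")) {
    blk <- bat$results[bat$results$analysis == an, ]
    expect_equal(blk$p_adj, bh_adjust(blk$p_raw), info = an)
  }
  expect_equal(nrow(bat$pairs), 3)
})
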