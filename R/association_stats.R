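#' Assemble a cohort frame from estimates, metadata and heteroplasmy calls
#'
#' Joins per-sample mtCN estimates with individual-level metadata and, when
#' available, per-site heteroplasmy calls, producing the substrate of the
#' association battery: one row per individual x tissue x method, with the
#' number of heteroplasmic sites per row counted from the heteroplasmy
#' table.
#'
#' @param estimates data.frame from [mtcn_from_coverage()] /
#'   [mtcn_from_ddpcr()], with `sample_id` equal to the individual
#'   identifier (or an `individual_id` column).
#' @param metadata data.frame with columns `individual_id`, `age`, `sex`
#'   (`"m"`/`"f"`), `haplogroup`.
#' @param heteroplasmy Optional data.frame with columns `individual_id`,
#'   `tissue`, `site`, `maf`.
#' @return data.frame with columns `individual_id`, `tissue`, `method`,
#'   `mtcn`, `age`, `sex`, `haplogroup`, `het_count`.
#' @export
build_cohort <- function(estimates, metadata, heteroplasmy = NULL) {
  est <- as.data.frame(estimates)
  if (is.null(est$individual_id)) est$individual_id <- est$sample_id
  keep <- c("individual_id", "tissue", "method", "mtcn")
  frame <- merge(est[keep],
                 metadata[c("individual_id", "age", "sex", "haplogroup")],
                 by = "individual_id")
  frame$het_count <- 0L
  if (!is.null(heteroplasmy) && nrow(heteroplasmy)) {
    cnt <- stats::aggregate(site ~ individual_id + tissue,
                            data = heteroplasmy, FUN = length)
    names(cnt)[3] <- "n_het"
    frame <- merge(frame, cnt, by = c("individual_id", "tissue"),
                   all.x = TRUE)
    frame$het_count <- ifelse(is.na(frame$n_het), 0L, frame$n_het)
    frame$n_het <- NULL
  }
  frame[order(frame$tissue, frame$individual_id), ]
}

#' Log-transform and normality-gate one tissue's mtCN values
#'
#' mtCN values of the requested tissue/method are log10-transformed, and
#' normality of the transformed values is tested with a Shapiro-Wilk test.
#' While the test rejects at `alpha_normality` and fewer than
#' `max_exclusions` samples have been removed, the sample with the largest
#' absolute z-score of log10 mtCN is excluded and the test repeated; this is
#' the gate that removes rare extreme-mtCN samples before correlation
#' analysis. All removals are logged. If normality is still rejected after
#' `max_exclusions` removals, analysis proceeds with a warning flag.
#'
#' @param frame Cohort data.frame (see [build_cohort()]).
#' @param tissue,method Which rows to prepare.
#' @param alpha_normality Shapiro-Wilk significance level (default 0.05).
#' @param max_exclusions Maximum samples removable by the gate (default 2).
#' @return List with `frame` (the retained rows, with a `log_mtcn` column),
#'   `exclusions` (data.frame `individual_id`, `tissue`, `reason`,
#'   `statistic` = the z-score, `shapiro_p` before removal) and
#'   `normality_ok`.
#' @export
prepare_tissue <- function(frame, tissue, method = "shotgun",
                           alpha_normality = 0.05, max_exclusions = 2) {
  sub <- frame[frame$tissue == tissue & frame$method == method, , drop = FALSE]
  if (nrow(sub) < 3) stop("fewer than 3 samples for ", tissue, "/", method)
  bad <- !is.finite(sub$mtcn) | sub$mtcn <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with non-positive mtCN dropped before ",
            "log transform")
    sub <- sub[!bad, , drop = FALSE]
  }
  sub$log_mtcn <- log10(sub$mtcn)
  excl <- data.frame(individual_id = character(), tissue = character(),
                     reason = character(), statistic = numeric(),
                     shapiro_p = numeric(), stringsAsFactors = FALSE)
  normality_ok <- TRUE
  repeat {
    sw <- stats::shapiro.test(sub$log_mtcn)
    if (sw$p.value >= alpha_normality) break
    if (nrow(excl) >= max_exclusions) {
      normality_ok <- FALSE
      warning("normality not achieved for ", tissue, "/", method, " after ",
              max_exclusions, " exclusions (Shapiro-Wilk p = ",
              signif(sw$p.value, 3), "); downstream results flagged")
      break
    }
    z <- (sub$log_mtcn - mean(sub$log_mtcn)) / stats::sd(sub$log_mtcn)
    i <- which.max(abs(z))
    excl <- rbind(excl, data.frame(
      individual_id = sub$individual_id[i], tissue = tissue,
      reason = "NORMALITY", statistic = z[i], shapiro_p = sw$p.value,
      stringsAsFactors = FALSE))
    sub <- sub[-i, , drop = FALSE]
  }
  list(frame = sub, exclusions = excl, normality_ok = normality_ok)
}

## one-row association result in the common column layout
assoc_row <- function(test_id, tissue, method, predictor, r, F, p, n) {
  data.frame(test_id = test_id, tissue = tissue, method = method,
             predictor = predictor, r = r, F = F, p_raw = p,
             p_adj = NA_real_, n = n, stringsAsFactors = FALSE)
}

empty_assoc <- function() {
  data.frame(test_id = character(), tissue = character(),
             method = character(), predictor = character(), r = numeric(),
             F = numeric(), p_raw = numeric(), p_adj = numeric(),
             n = integer(), stringsAsFactors = FALSE)
}

#' Simple regression / correlation of log10 mtCN with a predictor
#'
#' Fits a simple linear regression of `log_mtcn` on the predictor and
#' reports the Pearson correlation coefficient r, the regression
#' F-statistic and the two-sided p-value (F = t^2 for one predictor, so the
#' regression and correlation tests coincide).
#'
#' @param frame A prepared tissue frame (from [prepare_tissue()]`$frame`),
#'   or any data.frame with `log_mtcn` (computed from `mtcn` if absent).
#' @param predictor Column name of the predictor (`"age"`, `"het_count"`,
#'   or a MAF column added by the caller).
#' @param sex Optional `"m"`/`"f"` to restrict to one sex stratum.
#' @param age_range Optional `c(min, max)` filter on age (e.g. the over-50
#'   re-analysis).
#' @param mtcn_range Optional `c(min, max)` filter on mtCN (e.g. a
#'   threshold-split analysis of a high-copy subgroup).
#' @return One-row data.frame: `test_id`, `tissue`, `method`, `predictor`,
#'   `r`, `F`, `p_raw`, `p_adj` (NA here; filled by the caller's correction
#'   family), `n`.
#' @export
correlate <- function(frame, predictor, sex = NULL, age_range = NULL,
                      mtcn_range = NULL) {
  if (is.null(frame$log_mtcn)) frame$log_mtcn <- log10(frame$mtcn)
  if (!is.null(sex)) frame <- frame[frame$sex == sex, , drop = FALSE]
  if (!is.null(age_range))
    frame <- frame[frame$age >= age_range[1] & frame$age <= age_range[2], ,
                   drop = FALSE]
  if (!is.null(mtcn_range))
    frame <- frame[frame$mtcn >= mtcn_range[1] & frame$mtcn <= mtcn_range[2], ,
                   drop = FALSE]
  x <- frame[[predictor]]
  y <- frame$log_mtcn
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("fewer than 3 complete observations for '", predictor, "'")
  if (stats::sd(x) == 0) stop("predictor '", predictor, "' is constant")
  fit <- stats::lm(y ~ x)
  fs <- summary(fit)$fstatistic
  p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  assoc_row(paste0(predictor, if (!is.null(sex)) paste0("_", sex) else ""),
            frame$tissue[1], frame$method[1], predictor,
            r = stats::cor(x, y), F = unname(fs[1]), p = unname(p), n = n)
}

#' Group comparison of log10 mtCN (sex, haplogroup)
#'
#' One-way F-test of log10 mtCN between groups. For `factor = "sex"` this is
#' males vs females; for `factor = "haplogroup"` each major haplogroup in
#' `groups` is contrasted against the residual sample set (one test per
#' haplogroup). Contrasts with fewer than 2 samples in a group are skipped.
#' The signed correlation r reported for each contrast is the point-biserial
#' correlation of log10 mtCN with group membership.
#'
#' @param frame A prepared tissue frame.
#' @param factor `"sex"` or `"haplogroup"`.
#' @param groups Major haplogroups contrasted against the rest (default
#'   H, J, U).
#' @return data.frame of association rows (possibly 0 rows), with `p_adj`
#'   Benjamini-Hochberg-adjusted within the returned family for the
#'   haplogroup mode.
#' @export
group_compare <- function(frame, factor = c("sex", "haplogroup"),
                          groups = c("H", "J", "U")) {
  factor <- match.arg(factor)
  if (is.null(frame$log_mtcn)) frame$log_mtcn <- log10(frame$mtcn)
  one <- function(member, label) {
    if (sum(member) < 2 || sum(!member) < 2) return(NULL)
    y <- frame$log_mtcn
    if (stats::sd(y) == 0) {
      ## degenerate: identical values in both groups
      Fv <- 0; p <- 1; r <- 0
    } else {
      fit <- stats::lm(y ~ base::factor(member))
      fs <- summary(fit)$fstatistic
      Fv <- unname(fs[1])
      p <- unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
      r <- stats::cor(as.numeric(member), y)
    }
    assoc_row(label, frame$tissue[1], frame$method[1], label,
              r = r, F = Fv, p = p, n = nrow(frame))
  }
  rows <- if (factor == "sex") {
    list(one(frame$sex == "m", "sex"))
  } else {
    lapply(groups, function(g)
      one(frame$haplogroup == g, paste0("haplogroup_", g)))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_assoc())
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out
}

#' Pairwise inter-tissue correlation of mtCN
#'
#' Pearson correlation of log10 mtCN between every pair of tissues, matched
#' on individual, using pairwise-complete observations. P-values are
#' Benjamini-Hochberg-adjusted across all pairs within the method (the
#' correction family). Pairs with fewer than 3 complete observations are
#' reported with NA statistics.
#'
#' @param frame Cohort data.frame with `log_mtcn` (computed from `mtcn` if
#'   absent); typically each tissue has been through [prepare_tissue()] and
#'   the retained rows re-stacked.
#' @param method Which method's rows to use.
#' @return data.frame with one row per unordered tissue pair: `tissue1`,
#'   `tissue2`, `r`, `p_raw`, `p_adj`, `n`.
#' @export
tissue_pair_matrix <- function(frame, method = "shotgun") {
  frame <- frame[frame$method == method, , drop = FALSE]
  if (is.null(frame$log_mtcn)) frame$log_mtcn <- log10(frame$mtcn)
  tissues <- sort(unique(frame$tissue))
  if (length(tissues) < 2) stop("need at least 2 tissues")
  prs <- utils::combn(tissues, 2)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    t1 <- prs[1, k]; t2 <- prs[2, k]
    a <- frame[frame$tissue == t1, c("individual_id", "log_mtcn")]
    b <- frame[frame$tissue == t2, c("individual_id", "log_mtcn")]
    m <- merge(a, b, by = "individual_id")
    m <- m[stats::complete.cases(m), ]
    if (nrow(m) < 3)
      return(data.frame(tissue1 = t1, tissue2 = t2, r = NA_real_,
                        p_raw = NA_real_, p_adj = NA_real_, n = nrow(m),
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(m$log_mtcn.x, m$log_mtcn.y)
    data.frame(tissue1 = t1, tissue2 = t2, r = unname(ct$estimate),
               p_raw = ct$p.value, p_adj = NA_real_, n = nrow(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj[!is.na(out$p_raw)] <- bh_adjust(out$p_raw[!is.na(out$p_raw)])
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (monotone-enforced, capped at 1). Thin validated wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1] with no NA")
  stats::p.adjust(p_values, method = "BH")
}

#' Partial regression of log10 mtCN on several predictors
#'
#' Fits log10 mtCN on all predictors jointly and reports each predictor's
#' partial t-test p-value — the significance of that predictor with the
#' others held fixed, equivalent to regressing mtCN residuals on predictor
#' residuals. With a single predictor the partial p equals the simple
#' regression p from [correlate()] exactly.
#'
#' @param frame A prepared tissue frame containing the predictor columns.
#' @param predictors Character vector of predictor column names (e.g.
#'   `c("age", "maf_408", "het_count")`).
#' @return data.frame with one row per predictor: `tissue`, `method`,
#'   `predictor`, `estimate` (slope), `t`, `p_partial`, `n`.
#' @export
partial_regression <- function(frame, predictors) {
  if (is.null(frame$log_mtcn)) frame$log_mtcn <- log10(frame$mtcn)
  d <- frame[, c("log_mtcn", predictors), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(predictors) + 2)
    stop("need more than ", length(predictors) + 2, " observations")
  consts <- predictors[vapply(predictors,
                              function(p) stats::sd(d[[p]]) == 0, logical(1))]
  if (length(consts))
    stop("constant predictor(s): ", paste(consts, collapse = ", "))
  if (length(predictors) > 1) {
    cm <- abs(stats::cor(d[predictors]))
    diag(cm) <- 0
    if (any(cm > 1 - 1e-10)) {
      w <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      stop("collinear predictors: ", predictors[w[1]], " and ",
           predictors[w[2]])
    }
  }
  fit <- stats::lm(log_mtcn ~ ., data = d)
  co <- summary(fit)$coefficients
  out <- data.frame(tissue = frame$tissue[1], method = frame$method[1],
                    predictor = predictors,
                    estimate = co[predictors, "Estimate"],
                    t = co[predictors, "t value"],
                    p_partial = co[predictors, "Pr(>|t|)"],
                    n = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Associations between site-specific heteroplasmy MAF and mtCN
#'
#' Correlates the minor allele frequency at heteroplasmic sites with log10
#' mtCN in one tissue. Only sites carried by at least `min_carriers`
#' individuals are tested. For `arity = 1` each qualifying site is tested
#' across all samples, with non-carriers entered at MAF 0 (below the
#' detection floor); `carriers_only = TRUE` restricts to carriers. For
#' `arity` 2 or 3 the predictor is, per site combination, the combined MAF
#' (`combine`: sum, min or mean over member sites) among individuals
#' carrying *all* member sites, and combinations are filtered to at least
#' `min_carriers` joint carriers. P-values are Benjamini-Hochberg-adjusted
#' within each arity family.
#'
#' @param frame A prepared tissue frame.
#' @param heteroplasmy data.frame with `individual_id`, `tissue`, `site`,
#'   `maf` (carriers only).
#' @param min_carriers Minimum carriers per site / joint carriers per
#'   combination (default 10).
#' @param arity Test single sites (1), pairs (2) or triplets (3).
#' @param combine How member-site MAFs are combined for arity > 1
#'   (default `"sum"`).
#' @param carriers_only Restrict single-site tests to carriers.
#' @return data.frame of association rows with `predictor` naming the site
#'   (or `site1+site2(+site3)`) and `p_adj` adjusted within the family;
#'   0 rows (with a message) when no site qualifies.
#' @export
site_maf_tests <- function(frame, heteroplasmy, min_carriers = 10,
                           arity = 1, combine = c("sum", "min", "mean"),
                           carriers_only = FALSE) {
  combine <- match.arg(combine)
  stopifnot(arity %in% 1:3)
  if (is.null(frame$log_mtcn)) frame$log_mtcn <- log10(frame$mtcn)
  tis <- frame$tissue[1]
  het <- heteroplasmy[heteroplasmy$tissue == tis &
                        heteroplasmy$individual_id %in% frame$individual_id &
                        heteroplasmy$maf > 0, , drop = FALSE]
  empty <- empty_assoc()
  if (nrow(het) == 0) {
    message("no heteroplasmic sites in ", tis)
    return(empty)
  }
  carriers <- split(het$individual_id, het$site)
  sites <- names(carriers)[vapply(carriers, length, integer(1)) >= min_carriers]
  if (length(sites) < arity) {
    message("no site ", if (arity > 1) "combination " else "",
            "with >= ", min_carriers, " carriers in ", tis)
    return(empty)
  }
  maf_of <- function(site, ids) {
    m <- het[het$site == site, ]
    out <- m$maf[match(ids, m$individual_id)]
    ifelse(is.na(out), 0, out)
  }
  test_one <- function(label, ids, x) {
    sub <- frame[match(ids, frame$individual_id), ]
    if (length(x) < 3 || stats::sd(x) == 0) return(NULL)
    f <- sub[, c("tissue", "method", "log_mtcn")]
    f[[label]] <- x
    correlate(f, label)
  }
  rows <- if (arity == 1) {
    lapply(sites, function(s) {
      ids <- if (carriers_only) intersect(frame$individual_id, carriers[[s]])
             else frame$individual_id
      test_one(paste0("maf_", s), ids, maf_of(s, ids))
    })
  } else {
    combos <- utils::combn(sites, arity, simplify = FALSE)
    lapply(combos, function(cs) {
      joint <- Reduce(intersect, carriers[cs])
      joint <- intersect(frame$individual_id, joint)
      if (length(joint) < min_carriers) return(NULL)
      mm <- vapply(cs, function(s) maf_of(s, joint),
                   numeric(length(joint)))
      mm <- matrix(mm, nrow = length(joint))
      x <- switch(combine,
                  sum = rowSums(mm),
                  min = apply(mm, 1, min),
                  mean = rowMeans(mm))
      test_one(paste0("maf_", paste(cs, collapse = "+")), joint, x)
    })
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    message("no testable site combination in ", tis)
    return(empty)
  }
  out <- do.call(rbind, rows)
  out$tissue <- tis
  out$p_adj <- bh_adjust(out$p_raw)
  out
}

#' Run the full association battery on a cohort
#'
#' Convenience driver mirroring the complete statistical analysis: per
#' tissue, the normality gate, then age correlation (pooled and
#' sex-stratified), sex and haplogroup group comparisons, heteroplasmy-count
#' correlation and single-site MAF tests; plus the inter-tissue pair matrix.
#' Benjamini-Hochberg correction is applied within each analysis family
#' (one family per analysis x method, matching how method-specific corrected
#' p-values are usually reported).
#'
#' @param cohort Cohort data.frame (see [build_cohort()]).
#' @param heteroplasmy Heteroplasmy table (may be NULL).
#' @param method Which method's estimates to analyse.
#' @param min_carriers Carrier threshold for MAF tests.
#' @param alpha_normality,max_exclusions Passed to [prepare_tissue()].
#' @return List with `results` (tidy data.frame: `analysis`, `test_id`,
#'   `tissue`, `method`, `predictor`, `r`, `F`, `p_raw`, `p_adj`, `n`),
#'   `pairs` (the tissue-pair matrix), `exclusions` (normality-gate log)
#'   and `prepared` (the per-tissue prepared frames).
#' @export
association_battery <- function(cohort, heteroplasmy = NULL,
                                method = "shotgun", min_carriers = 10,
                                alpha_normality = 0.05, max_exclusions = 2) {
  tissues <- sort(unique(cohort$tissue))
  prepared <- list()
  exclusions <- list()
  fam <- list(age = list(), sex = list(), haplogroup = list(),
              het_count = list(), maf = list())
  for (tis in tissues) {
    pt <- prepare_tissue(cohort, tis, method,
                         alpha_normality = alpha_normality,
                         max_exclusions = max_exclusions)
    prepared[[tis]] <- pt$frame
    exclusions[[tis]] <- pt$exclusions
    f <- pt$frame
    fam$age[[tis]] <- correlate(f, "age")
    fam$sex[[tis]] <- group_compare(f, "sex")
    fam$haplogroup[[tis]] <- group_compare(f, "haplogroup")
    if (stats::sd(f$het_count) > 0)
      fam$het_count[[tis]] <- correlate(f, "het_count")
    if (!is.null(heteroplasmy))
      fam$maf[[tis]] <- suppressMessages(
        site_maf_tests(f, heteroplasmy, min_carriers = min_carriers))
  }
  res <- list()
  for (an in names(fam)) {
    rows <- fam[[an]][!vapply(fam[[an]], is.null, logical(1))]
    rows <- rows[vapply(rows, nrow, integer(1)) > 0]
    if (!length(rows)) next
    block <- do.call(rbind, rows)
    block$analysis <- an
    ## correction family: one per analysis (within this method); the MAF
    ## family is corrected per tissue inside site_maf_tests already
    if (an != "maf") block$p_adj <- bh_adjust(block$p_raw)
    res[[an]] <- block
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  results <- results[, c("analysis", "test_id", "tissue", "method",
                         "predictor", "r", "F", "p_raw", "p_adj", "n")]
  stacked <- do.call(rbind, prepared)
  pairs <- if (length(tissues) >= 2) tissue_pair_matrix(stacked, method)
           else NULL
  list(results = results, pairs = pairs,
       exclusions = do.call(rbind, exclusions), prepared = prepared)
}
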