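test_that("probe mapping respects half-open bounds and partitions probes", {
  man <- data.frame(probe_id = paste0("cg", 1:5), chrom = "chr1",
                    pos = c(1500, 2000, 999, 4000, 7000),
                    stringsAsFactors = FALSE)
  pm <- mapProbes(man, mkStates(),
                  clusters = data.frame(region_id = "BIV_00001",
                                        cluster = 2L))
  expect_equal(as.character(pm$category),
               c("bivalent", "none", "none", "K4only", "none"))
  expect_equal(pm$cluster, c(2L, NA, NA, NA, NA))
  expect_equal(pm$region_id[1], "BIV_00001")
  expect_equal(sum(table(pm$category)), nrow(man))
})

test_that("probe mapping agrees with a per-probe linear scan", {
  set.seed(80)
  len <- 100000L
  starts <- seq(0, len - 3000, by = 2500)
  keep <- sample(c(TRUE, FALSE), length(starts), replace = TRUE)
  starts <- starts[keep]
  r <- bedRanges("chr1", starts, starts + 1200)
  r$region_id <- sprintf("R%03d", seq_along(r))
  r$category <- factor(sample(c("bivalent", "K4only", "K27only"),
                              length(r), replace = TRUE),
                       levels = c("bivalent", "K4only", "K27only"))
  man <- data.frame(probe_id = sprintf("cg%05d", 1:500), chrom = "chr1",
                    pos = sample.int(len, 500) - 1L,
                    stringsAsFactors = FALSE)
  pm <- mapProbes(man, r)
  for (i in seq_len(nrow(man))) {
    inside <- which(starts <= man$pos[i] & man$pos[i] < starts + 1200)
    want <- if (length(inside)) as.character(r$category[inside]) else "none"
    expect_equal(as.character(pm$category[i]), want)
  }
})

test_that("beta bands partition values with the stated boundary conventions", {
  b <- c(0.05, 0.5, 0.8, 0.3, 0.7, 0.1, NA)
  band <- betaCategories(b)
  expect_equal(as.character(band),
               c("<0.1", "[0.3,0.7]", ">0.7", "[0.3,0.7]", "[0.3,0.7]",
                 "[0.1,0.3)", NA))
  expect_equal(sum(table(band)), sum(!is.na(b)))
  expect_error(betaCategories(c(0.2, 1.4)), "\\[0, 1\\]")
  cats <- factor(c("bivalent", "none", "none", "K4only", "K27only",
                   "bivalent", "none"))
  tb <- attr(betaCategories(b, cats), "table")
  expect_equal(sum(tb), sum(!is.na(b)))
})

test_that("moderated t equals ordinary t when all probe variances are equal", {
  # identical within-group deviation patterns -> identical sample variances
  n1 <- 5L; n2 <- 5L
  dev <- c(-2, -1, 0, 1, 2) / 10
  shift <- seq(0, 2, length.out = 40)
  beta <- t(vapply(shift, function(s) c(dev + s, dev), numeric(n1 + n2)))
  rownames(beta) <- sprintf("p%02d", seq_along(shift))
  status <- rep(c("tumor", "normal"), c(n1, n2))
  res <- moderatedTTest(beta, status)
  s2 <- (sum(dev^2) * 2) / (n1 + n2 - 2)
  tOrd <- (shift) / sqrt(s2 * (1 / n1 + 1 / n2))
  expect_equal(res$t_mod, tOrd, tolerance = 1e-12)
  expect_true(is.infinite(attr(res, "d0")))
})

test_that("d0 = 0 gives the ordinary t exactly, including its p-value", {
  set.seed(81)
  beta <- matrix(runif(50 * 12, 0.2, 0.8), nrow = 50,
                 dimnames = list(sprintf("p%02d", 1:50), NULL))
  status <- rep(c("tumor", "normal"), each = 6)
  res <- moderatedTTest(beta, status, d0 = 0)
  for (i in c(1, 17, 50)) {
    tt <- t.test(beta[i, status == "tumor"], beta[i, status == "normal"],
                 var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("moderated t matches the limma empirical-Bayes reference", {
  skip_if_not_installed("limma")
  set.seed(82)
  n <- 1500L
  s2true <- 0.02 * 8 / rchisq(n, df = 8)
  x <- matrix(rnorm(n * 11, 0, sqrt(s2true)), nrow = n,
              dimnames = list(sprintf("p%04d", 1:n), NULL))
  x[1:80, 1:6] <- x[1:80, 1:6] + 0.3
  status <- rep(c("tumor", "normal"), c(6, 5))
  res <- moderatedTTest(x, status)
  fit <- limma::eBayes(limma::lmFit(x, cbind(1, status == "tumor")))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("probes with too few observations are flagged, not tested", {
  beta <- matrix(runif(3 * 8, 0.3, 0.6), nrow = 3,
                 dimnames = list(c("a", "b", "c"), NULL))
  beta[2, 1:3] <- NA   # only 1 tumor value left
  status <- rep(c("tumor", "normal"), each = 4)
  res <- moderatedTTest(beta, status)
  expect_true(is.na(res$t_mod[2]))
  expect_false(anyNA(res$t_mod[c(1, 3)]))
  expect_error(moderatedTTest(beta, rep("case", 8)), "unknown status")
})

test_that("BH q-values match the brute-force step-up definition", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.37), 0.37)
  bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m))
      q[o[i]] <- min(vapply(i:m, function(k) p[o[k]] * m / k, numeric(1)), 1)
    q
  }
  set.seed(83)
  for (rep in 1:50) {
    p <- runif(sample(2:200, 1))
    q <- bhFdr(p)
    expect_equal(q, bruteBH(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # order preserving
  }
})

test_that("DMP calls follow the delta/FDR rule with the sign convention", {
  res <- data.frame(probe_id = c("a", "b", "c", "d"),
                    delta_beta = c(0.30, 0.30, -0.30, 0.10),
                    t_mod = 1, df = 10,
                    p = c(1e-6, 0.9, 1e-6, 1e-6))
  called <- callDmps(res)
  expect_equal(as.character(called$call), c("hyper", "none", "hypo", "none"))
})

test_that("CIMP arms are analyzed separately on disjoint tumors", {
  study <- local({
    spec <- genomeSpec(seed = 16, nBivalent = 30, nK4only = 30,
                       nK27only = 20, nGenes = 120)
    ann <- simulateAnnotations(spec)
    simulateMethylomes(ann$truth, nProbes = 4000L, nPairs = 10L,
                       nTypes = 2L, nSharedHyper = 60L, nPosExtra = 40L,
                       nNegExtra = 10L, nHypo = 10L, nPanCancer = 20L,
                       panTypes = 2L)
  })
  arms <- stratifyCimp(study$beta, study$samples, "T01")
  expect_setequal(names(arms), c("positive", "negative"))
  hyPos <- arms$positive$probe_id[arms$positive$call == "hyper"]
  hyNeg <- arms$negative$probe_id[arms$negative$call == "hyper"]
  # the arm-specific extras appear only in their own arm
  posOnly <- setdiff(study$truth$hyper_pos$T01, study$truth$hyper_shared$T01)
  expect_gt(mean(posOnly %in% hyPos), 0.9)
  expect_equal(sum(posOnly %in% hyNeg), 0L)
  # all tumors in one arm -> the other arm is absent
  sheet <- study$samples
  sheet$cimp[sheet$status == "tumor"] <- "positive"
  arms2 <- stratifyCimp(study$beta, sheet, "T01")
  expect_named(arms2, "positive")
})

test_that("category distributions report fractions, clusters and a reference", {
  pm <- data.frame(probe_id = paste0("cg", 1:10),
                   category = factor(c(rep("bivalent", 4), rep("none", 4),
                                       "K4only", "K27only"),
                                     levels = c("none", "bivalent",
                                                "K4only", "K27only")),
                   region_id = NA_character_,
                   cluster = c(2L, 2L, 2L, 3L, rep(NA_integer_, 6)))
  calls <- data.frame(probe_id = paste0("cg", 1:10),
                      call = factor(c(rep("hyper", 4), "hypo",
                                      rep("none", 5)),
                                    levels = c("hyper", "hypo", "none")))
  cd <- categoryDistribution(calls, pm)
  expect_equal(sum(cd$hyper), 1)
  expect_equal(unname(cd$hyper["bivalent"]), 1)
  expect_equal(unname(cd$hypo["none"]), 1)
  expect_equal(unname(cd$hyper_clusters["cluster2"]), 0.75)
  expect_equal(sum(cd$reference), 1)
  # no calls at all -> absent, not zeros
  none <- calls
  none$call[] <- "none"
  cdNone <- categoryDistribution(none, pm)
  expect_null(cdNone$hyper)
  expect_null(cdNone$hypo)
})

test_that("recurrence applies the >= minTypes rule and is monotone", {
  sets <- list(A = c("p1", "p2"), B = c("p1", "p2"), C = c("p1", "p2"),
               D = c("p1", "p2"), E = c("p1"), F = c("p1"),
               G = character(), H = c("p3"))
  rec <- recurrence(sets, minTypes = 5)
  expect_equal(rec$probes, "p1")       # p1 in 6 types, p2 in 4, p3 in 1
  expect_equal(rec$counts[["p2"]], 4L)
  prev <- Inf
  for (mt in 1:6) {
    cur <- length(recurrence(sets, minTypes = mt)$probes)
    expect_lte(cur, prev)
    prev <- cur
  }
  # exact-boundary membership: 5 of 8 is recurrent, 4 of 8 is not
  sets2 <- c(lapply(1:5, function(i) "q1"), lapply(1:3, function(i) "q2"))
  rec2 <- recurrence(sets2, minTypes = 5)
  expect_equal(rec2$probes, "q1")
})
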