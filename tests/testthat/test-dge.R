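test_that("TPM and RPKM follow their defining arithmetic", {
  expect_equal(normalize_tpm(50, 500000), 100)
  expect_equal(normalize_tpm(0, 123), 0)
  expect_error(normalize_tpm(1, 0), "positive")

  expect_equal(normalize_rpkm(10, 500, 1e6), 20)
  expect_equal(normalize_rpkm(0, 500, 1e6), 0)
  # doubling length halves RPKM at fixed count
  expect_equal(normalize_rpkm(7, 800, 2e6), 2 * normalize_rpkm(7, 1600, 2e6))
  expect_error(normalize_rpkm(1, 0, 1e6), "length")
  expect_error(normalize_rpkm(1, 100, 0), "total")

  # TPM columns sum to 1e6 x (column counts / library total)
  cm <- matrix(c(10L, 40L, 0L, 30L, 20L, 50L), 3,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  ex <- toy_expr(cm, totals = c(a = 200, b = 400))
  expect_equal(colSums(tpm(ex)), 1e6 * colSums(cm) / c(a = 200, b = 400))
})

test_that("Audic-Claverie p-value matches closed forms and symmetry", {
  # perfectly balanced null
  expect_equal(audic_claverie_p(0, 1e5, 0, 1e5), 1)
  # single lower-tail term: p(0|10) with N1=N2 is 2^-11, two-sided 2^-10
  expect_lt(abs(audic_claverie_p(10, 1e6, 0, 1e6) - 2^-10), 1e-12)
  # swapping libraries complements the conditional tail exactly
  # (lower' = 1 - lower by negative-binomial/binomial duality); the
  # two-sided value then differs only by the observed-point mass
  set.seed(42)
  for (rep in 1:50) {
    x <- sample(0:200, 1); y <- sample(0:200, 1)
    n1 <- sample(c(1e5, 1e6, 3e6), 1); n2 <- sample(c(1e5, 1e6, 3e6), 1)
    lower <- pnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
    lower_compl <- pnbinom(y, size = x + 1, prob = n1 / (n1 + n2),
                           lower.tail = FALSE)
    point_sw <- dnbinom(x, size = y + 1, prob = n2 / (n1 + n2))
    expected_sw <- min(1, 2 * min(lower_compl, lower + point_sw))
    expect_equal(audic_claverie_p(y, n2, x, n1), expected_sw,
                 tolerance = 1e-9)
  }
  expect_error(audic_claverie_p(-1, 1e5, 0, 1e5), "non-negative")
})

test_that("Audic-Claverie agrees with the negative-binomial tail identity", {
  # independent oracle: the conditional law p(k|x) is NB(x+1, N1/(N1+N2)),
  # so the lower tail is pnbinom, the upper tail its accurate complement
  oracle <- function(x, n1, y, n2) {
    pr <- n1 / (n1 + n2)
    lower <- pnbinom(y, size = x + 1, prob = pr)
    upper <- if (y == 0) 1 else
      pnbinom(y - 1, size = x + 1, prob = pr, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  }
  set.seed(7)
  for (rep in 1:300) {
    x <- sample(0:100, 1); y <- sample(0:100, 1)
    n1 <- sample(c(1e5, 1e6, 3e6), 1); n2 <- sample(c(1e5, 1e6, 3e6), 1)
    o <- oracle(x, n1, y, n2)
    expect_lt(abs(audic_claverie_p(x, n1, y, n2) - o) / o, 1e-9)
  }
  # moderate counts, unequal depths
  for (rep in 1:50) {
    x <- sample(0:5000, 1); y <- sample(0:5000, 1)
    n1 <- sample(c(1e5, 1e6, 3e6), 1); n2 <- sample(c(1e5, 1e6, 3e6), 1)
    o <- oracle(x, n1, y, n2)
    if (o > 1e-280) {
      expect_lt(abs(audic_claverie_p(x, n1, y, n2) - o) / o, 1e-9)
    }
  }
  # stable at large counts
  big <- audic_claverie_p(1e6, 3e6, 999000, 3e6)
  expect_true(is.finite(big) && big > 0 && big <= 1)
  expect_lt(abs(big - oracle(1e6, 3e6, 999000, 3e6)) /
              oracle(1e6, 3e6, 999000, 3e6), 1e-8)
})

test_that("p is monotone non-increasing in count imbalance at fixed x+y", {
  # monotone within each side of the balance point y*N1 = x*N2 (the two
  # tails of the discrete conditional law are not comparable across sides)
  for (n2 in c(1e5, 1e6, 3e6)) {
    for (s in c(20, 60)) {
      n1 <- 1e6
      xs <- 0:s
      p <- audic_claverie_p(xs, n1, s - xs, n2)
      d <- (s - xs) * n1 - xs * n2
      for (side in list(d >= 0, d <= 0)) {
        pp <- p[side]
        o <- order(abs(d[side]))
        expect_true(all(diff(pp[o]) <= 1e-12))
      }
    }
  }
})

test_that("BH step-up matches hand calculation and an independent oracle", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")

  # independent step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    out <- numeric(m)
    out[o] <- q
    out
  }
  set.seed(99)
  for (rep in 1:1000) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, step_up(p))
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("call_de tests nonzero genes and partitions significants", {
  cm <- matrix(c(100L, 0L, 50L, 0L,
                 100L, 40L, 5L, 0L), ncol = 2,
               dimnames = list(paste0("g", 1:4), c("ctl", "case")))
  ex <- toy_expr(cm, totals = c(ctl = 1e5, case = 1e5))
  des <- comparison_design("case", "ctl")
  de <- call_de(ex, des, fdr_threshold = 0.05, log2_threshold = 0.5)
  r <- de$results[[1]]
  # g4 is zero in both libraries: excluded from the tested family
  expect_identical(r$gene, c("g1", "g2", "g3"))
  # identical counts at equal totals: ratio 0, never significant
  expect_equal(r$log2_ratio[r$gene == "g1"], 0)
  expect_false(r$significant[r$gene == "g1"])
  s <- de_summary(de)
  expect_identical(s$up + s$down, sum(r$significant))
  expect_error(call_de(ex, comparison_design("case", "nope")), "missing")
})

test_that("an 8-fold simulated gene is called in the stage-4 comparison", {
  d <- small_design(n_genes = 300, library_depth = 60000, seed = 21)
  sim <- simulate_experiment(d)
  idx <- build_tag_index(sim$reference)
  maps <- lapply(lapply(sim$libraries, filter_raw_tags), map_tags,
                 index = idx)
  de <- call_de(expression_matrix(maps))
  truth <- sim$reference$truth
  # pick abundant truly-DE genes: detection is guaranteed at high counts
  strong <- truth$gene[truth$is_de &
                         truth$abundance > stats::median(truth$abundance)]
  r <- de$results[["stage4_vs_mutant"]]
  called <- r$gene[r$significant]
  expect_gte(mean(strong %in% called), 0.9)
  # significant calls are enriched in truth DE genes
  expect_gt(mean(called %in% truth$gene[truth$is_de]), 0.8)
})

test_that("intersection is the exact set intersection", {
  expect_identical(intersect_comparisons(list(c("A", "B"), c("B", "C"))), "B")
  expect_identical(intersect_comparisons(list(c("A", "B"), character(0))),
                   character(0))
  expect_error(intersect_comparisons(list()), "at least one")
})

test_that("extreme screen requires the threshold in all comparisons with one sign", {
  prof <- rbind(up = c(11, 11, 12, 11, 11, 11),
                mixed = c(11, -11, 12, 11, 11, 11),
                dip = c(9, 11, 12, 11, 11, 11),
                down = c(-11, -12, -11, -11, -11, -13))
  out <- screen_extremes(prof, threshold = 10)
  expect_identical(out$up, "up")
  expect_identical(out$down, "down")
  expect_error(screen_extremes(rbind(c(1, NA))), "complete")
})

test_that("trend clustering separates blobs and ignores input order", {
  set.seed(5)
  blob1 <- matrix(rnorm(60, mean = 8, sd = 0.3), 10)
  blob2 <- matrix(rnorm(60, mean = -8, sd = 0.3), 10)
  prof <- rbind(blob1, blob2)
  rownames(prof) <- sprintf("g%02d", 1:20)
  cl <- cluster_trends(prof, k = 2)
  g <- cl$groups
  expect_length(unique(g[sprintf("g%02d", 1:10)]), 1L)
  expect_length(unique(g[sprintf("g%02d", 11:20)]), 1L)
  expect_false(g[["g01"]] == g[["g11"]])

  # permutation invariance of the partition
  perm <- sample(nrow(prof))
  cl2 <- cluster_trends(prof[perm, ], k = 2)
  expect_identical(cl$groups[sort(rownames(prof))],
                   cl2$groups[sort(rownames(prof))])

  # k = n gives singletons; k > n errors
  cln <- cluster_trends(prof, k = nrow(prof))
  expect_length(unique(cln$groups), nrow(prof))
  expect_error(cluster_trends(prof, k = 21), "exceeds")
})
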