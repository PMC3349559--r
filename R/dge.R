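ac_term_log <- function(k, x, lq, l1q) {
  lchoose(x + k, k) + k * lq - (x + k + 1) * l1q
}

# log of the upper tail sum_{k >= y} p(k|x), summed directly in chunks;
# avoids the catastrophic cancellation of 1 - lower when lower ~ 1
ac_upper_log <- function(x, y, lq, l1q) {
  mode_k <- (x + 1) * exp(lq) # terms decay geometrically beyond this
  acc <- -Inf
  k0 <- y
  chunk <- 256L
  repeat {
    ks <- seq.int(k0, k0 + chunk - 1L)
    lt <- ac_term_log(ks, x, lq, l1q)
    acc <- logsumexp(c(acc, lt))
    k0 <- k0 + chunk
    if (k0 > mode_k && max(lt) < acc - 45) break
    chunk <- min(chunk * 2L, 16384L)
  }
  acc
}

ac_p_one <- function(x, n1, y, n2) {
  lq <- log(n2) - log(n1)
  l1q <- log1p(n2 / n1)
  lower <- min(exp(logsumexp(ac_term_log(0:y, x, lq, l1q))), 1)
  if (lower < 0.5) {
    # the upper tail contains the balance point, so it exceeds 1/2 and the
    # doubled minimum is determined by the lower tail alone
    return(max(2 * lower, .Machine$double.xmin))
  }
  upper <- min(exp(ac_upper_log(x, y, lq, l1q)), 1)
  p <- 2 * min(lower, upper)
  min(1, max(p, .Machine$double.xmin))
}

#' Audic-Claverie two-sided p-value for digital expression counts
#'
#' Exact test for the difference of a tag count between two libraries of
#' known sizes.  Under the null of equal relative expression, the
#' probability of observing `y` copies in library 2 given `x` copies in
#' library 1 is
#' `p(y|x) = (N2/N1)^y * (x+y)! / (x! * y! * (1 + N2/N1)^(x+y+1))`.
#' The lower tail is `sum_{k <= y} p(k|x)`, the upper tail is
#' `1 - lower + p(y|x)`, and the two-sided p-value is
#' `min(1, 2 * min(lower, upper))` — the symmetric convention consistent
#' with calling both up- and downregulation.  All terms are accumulated in
#' log space; the computation is stable for counts up to 1e6.
#'
#' @param x,y Non-negative integer counts in libraries 1 and 2 (vectors are
#'   recycled to a common length).
#' @param n1,n2 Positive library totals (total clean tags).
#' @return Numeric vector of two-sided p-values in (0, 1\].
#' @export
audic_claverie_p <- function(x, n1, y, n2) {
  len <- max(length(x), length(y), length(n1), length(n2))
  if (!len) return(numeric(0))
  x <- rep_len(x, len); y <- rep_len(y, len)
  n1 <- rep_len(n1, len); n2 <- rep_len(n2, len)
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y)))
    stopf("counts x and y must be non-negative integers")
  if (any(n1 <= 0) || any(n2 <= 0))
    stopf("library totals must be positive")
  vapply(seq_len(len), function(i) ac_p_one(x[i], n1[i], y[i], n2[i]),
         numeric(1))
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard step-up adjustment (via [stats::p.adjust()]): q-values are
#' monotone non-decreasing in p-rank and capped at 1.
#'
#' @param p Numeric vector of p-values in (0, 1\].
#' @return Numeric vector of q-values; empty input gives empty output.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stopf("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Define the case/control comparison pairs
#'
#' @param case,control Equal-length character vectors of library labels;
#'   each pair must reference two distinct libraries.
#' @return Data frame of class `comparison_design` with columns
#'   `comparison`, `case`, `control`.
#' @export
comparison_design <- function(case, control) {
  if (length(case) != length(control) || !length(case))
    stopf("case and control must be non-empty vectors of equal length")
  if (any(case == control))
    stopf("a comparison must reference two distinct libraries")
  out <- data.frame(comparison = paste0(case, "_vs_", control),
                    case = case, control = control,
                    stringsAsFactors = FALSE)
  class(out) <- c("comparison_design", "data.frame")
  out
}

#' The default six staged comparisons
#'
#' With libraries ordered baseline-mutant first and stages after, stages 2
#' and up are each compared against the mutant baseline and against stage 1,
#' in the order stage2/mutant, stage3/mutant, ..., stage2/stage1,
#' stage3/stage1, ... (six comparisons for a five-library design).
#'
#' @param libraries Character vector of library labels (>= 3).
#' @return A [comparison_design()].
#' @export
default_comparisons <- function(libraries) {
  if (length(libraries) < 3)
    stopf("need at least 3 libraries for the staged design")
  stages <- libraries[-(1:2)]
  comparison_design(case = rep(stages, 2),
                    control = rep(libraries[c(1L, 2L)],
                                  each = length(stages)))
}

#' Call differentially expressed genes across a comparison design
#'
#' For each comparison, every gene with a nonzero count in either library
#' is tested with [audic_claverie_p()] on raw counts; q-values are computed
#' by [bh_fdr()] within the comparison's tested family (genes at zero in
#' both libraries are excluded from the family).  The log2 ratio is taken
#' on tags-per-million with a pseudocount added to the raw counts for the
#' ratio only, so genes at zero in one library get a finite ratio.  A gene
#' is significant when `fdr < fdr_threshold` and
#' `|log2_ratio| > log2_threshold`.
#'
#' @param expr An [expression_matrix()].
#' @param design A [comparison_design()]; defaults to
#'   [default_comparisons()] over the matrix columns.
#' @param fdr_threshold FDR cut-off (default 0.001).
#' @param log2_threshold Absolute log2-ratio cut-off (default 1).
#' @param pseudocount Added to raw counts for the ratio (default 0.5).
#' @return Object of class `dge_result`: list with `results` (one data
#'   frame per comparison: gene, x, y, n1, n2, log2_ratio, p_value, fdr,
#'   significant), the `design` and the thresholds.
#' @export
call_de <- function(expr, design = NULL, fdr_threshold = 0.001,
                    log2_threshold = 1, pseudocount = 0.5) {
  stopifnot(inherits(expr, "expr_matrix"))
  libs <- colnames(expr$counts)
  if (is.null(design)) design <- default_comparisons(libs)
  missing <- setdiff(unique(c(design$case, design$control)), libs)
  if (length(missing))
    stopf("comparison references missing library: %s", missing[1L])
  results <- lapply(seq_len(nrow(design)), function(r) {
    ctl <- design$control[r]; cas <- design$case[r]
    x <- expr$counts[, ctl]; y <- expr$counts[, cas]
    n1t <- unname(expr$lib_totals[ctl]); n2t <- unname(expr$lib_totals[cas])
    keep <- which(x + y > 0)
    p <- audic_claverie_p(x[keep], n1t, y[keep], n2t)
    fdr <- bh_fdr(p)
    lr <- log2(((y[keep] + pseudocount) / n2t) /
                 ((x[keep] + pseudocount) / n1t))
    sig <- fdr < fdr_threshold & abs(lr) > log2_threshold
    data.frame(gene = rownames(expr$counts)[keep],
               x = unname(x[keep]), y = unname(y[keep]),
               n1 = n1t, n2 = n2t, log2_ratio = unname(lr),
               p_value = p, fdr = fdr, significant = unname(sig),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(results) <- design$comparison
  structure(list(results = results, design = design,
                 fdr_threshold = fdr_threshold,
                 log2_threshold = log2_threshold,
                 pseudocount = pseudocount),
            class = "dge_result")
}

#' @export
print.dge_result <- function(x, ...) {
  print(de_summary(x))
  invisible(x)
}

#' Up/down counts per comparison
#'
#' @param res A `dge_result`.
#' @return Data frame: comparison, tested, up, down (up = significant with
#'   positive log2 ratio).
#' @export
de_summary <- function(res) {
  stopifnot(inherits(res, "dge_result"))
  rows <- lapply(names(res$results), function(nm) {
    d <- res$results[[nm]]
    data.frame(comparison = nm, tested = nrow(d),
               up = sum(d$significant & d$log2_ratio > 0),
               down = sum(d$significant & d$log2_ratio < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes significant in every comparison
#'
#' Exact set intersection of the per-comparison significant gene sets.
#'
#' @param x A `dge_result` or a list of character vectors of gene ids.
#' @return Sorted character vector (possibly empty).
#' @export
intersect_comparisons <- function(x) {
  sets <- if (inherits(x, "dge_result")) {
    lapply(x$results, function(d) d$gene[d$significant])
  } else {
    x
  }
  if (!length(sets)) stopf("need at least one comparison")
  sort(unique(Reduce(intersect, sets)))
}

#' Log2-ratio trend profiles over the comparison design
#'
#' @param res A `dge_result`.
#' @param genes Gene ids to profile; defaults to
#'   [intersect_comparisons()] of `res`.
#' @return Numeric gene x comparison matrix of log2 ratios (NA where a gene
#'   was untested in a comparison).
#' @export
trend_profiles <- function(res, genes = intersect_comparisons(res)) {
  stopifnot(inherits(res, "dge_result"))
  prof <- vapply(res$results, function(d) {
    d$log2_ratio[match(genes, d$gene)]
  }, numeric(length(genes)))
  if (length(genes) == 1L) prof <- matrix(prof, nrow = 1L,
                                          dimnames = list(genes,
                                                          names(res$results)))
  else rownames(prof) <- genes
  prof
}

#' Screen for extreme, sign-consistent expression trajectories
#'
#' Keeps genes whose absolute log2 ratio exceeds `threshold` in every
#' comparison with a consistent sign: the up-set requires every ratio above
#' `threshold`, the down-set every ratio below `-threshold`.  Genes mixing
#' signs (or dipping below the threshold anywhere) are excluded.
#'
#' @param profiles Gene x comparison matrix from [trend_profiles()]
#'   (no missing ratios allowed).
#' @param threshold Absolute log2 ratio cut-off (default 10).
#' @return List with character vectors `up` and `down`.
#' @export
screen_extremes <- function(profiles, threshold = 10) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles)) stopf("profiles must be complete (no missing ratios)")
  up <- rowSums(profiles > threshold) == ncol(profiles)
  down <- rowSums(profiles < -threshold) == ncol(profiles)
  list(up = rownames(profiles)[up], down = rownames(profiles)[down])
}

#' Cluster trend profiles into expression groups
#'
#' Hierarchical agglomerative clustering of the log2-ratio vectors
#' (Euclidean distance, average linkage by default), cut into `k` groups.
#' Rows are sorted by gene id before clustering so the partition does not
#' depend on input order.
#'
#' @param profiles Gene x comparison matrix (complete).
#' @param k Number of groups (default 4; must not exceed the number of
#'   profiles).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `groups` (named integer vector of group labels, in
#'   sorted gene order) and `tree` (the `hclust` object).
#' @export
cluster_trends <- function(profiles, k = 4, linkage = "average") {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles)) stopf("profiles must be complete (no missing ratios)")
  if (k > nrow(profiles))
    stopf("k (%d) exceeds the number of profiles (%d)", k, nrow(profiles))
  m <- profiles[order(rownames(profiles)), , drop = FALSE]
  tree <- hclust(dist(m), method = linkage)
  groups <- cutree(tree, k = k)
  list(groups = groups, tree = tree)
}
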