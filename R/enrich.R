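#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability that at least `m` of `n` screened genes fall in a term of
#' size `M` within an annotated background of `N` genes:
#' `P = 1 - sum_{i=0}^{m-1} choose(M, i) * choose(N - M, n - i) /
#' choose(N, n)`, i.e. one minus the hypergeometric CDF at `m - 1`,
#' evaluated from the lower-tail sum in log space.  `m = 0` gives `P = 1`
#' (empty sum), and `M = N` gives `P = 1` for any `m <= n`.
#'
#' @param N Background: number of genes with an annotation.
#' @param n Number of screened (differentially expressed) genes within `N`.
#' @param M Number of genes annotated to the term.
#' @param m Number of screened genes annotated to the term.
#' @return Numeric vector of upper-tail p-values in \[0, 1\]; arguments are
#'   recycled to a common length.
#' @export
hypergeom_enrich_p <- function(N, n, M, m) {
  len <- max(length(N), length(n), length(M), length(m))
  if (!len) return(numeric(0))
  N <- rep_len(N, len); n <- rep_len(n, len)
  M <- rep_len(M, len); m <- rep_len(m, len)
  for (v in list(N = N, n = n, M = M, m = m)) {
    if (any(v < 0) || any(v != floor(v)))
      stopf("violated bound: all of N, n, M, m must be non-negative integers")
  }
  if (any(M > N)) stopf("violated bound: M <= N")
  if (any(n > N)) stopf("violated bound: n <= N")
  if (any(m > pmin(n, M))) stopf("violated bound: m <= min(n, M)")
  vapply(seq_len(len), function(j) {
    if (m[j] == 0L) return(1)
    i <- 0:(m[j] - 1L)
    lt <- lchoose(M[j], i) + lchoose(N[j] - M[j], n[j] - i) -
      lchoose(N[j], n[j])
    min(max(1 - exp(logsumexp(lt)), 0), 1)
  }, numeric(1))
}

#' Term enrichment of a screened gene set with Bonferroni correction
#'
#' The background `N` is the set of genes carrying at least one annotation
#' in the supplied table (restricted to `ontology` when given); the
#' screened set is intersected with that background first.  One
#' hypergeometric test is run per term containing at least one screened
#' gene; Bonferroni multiplies raw p-values by the number of tested terms
#' (or by all terms, when `divisor = "all"`), capped at 1.  A term is
#' enriched when its corrected p-value falls below `alpha`.
#'
#' @param genes Character vector of screened gene ids.
#' @param annotation Data frame with columns `gene`, `term` and optionally
#'   `ontology`.
#' @param ontology Optional ontology filter (e.g. `"GO"` or `"KO"`).
#' @param alpha Corrected-p threshold for the enriched flag (default 0.05).
#' @param divisor `"tested"` (default) or `"all"`: the Bonferroni divisor.
#' @return Data frame sorted by corrected then raw p: `term`, `ontology`,
#'   `N`, `n`, `M`, `m`, `p_value`, `p_bonferroni`, `enriched`.  Empty (with
#'   a warning) when no screened gene carries an annotation.
#' @export
enrich_terms <- function(genes, annotation, ontology = NULL, alpha = 0.05,
                         divisor = c("tested", "all")) {
  divisor <- match.arg(divisor)
  if (!all(c("gene", "term") %in% names(annotation)))
    stopf("annotation must carry columns 'gene' and 'term'")
  if (!"ontology" %in% names(annotation)) annotation$ontology <- NA_character_
  if (!is.null(ontology))
    annotation <- annotation[annotation$ontology %in% ontology, , drop = FALSE]
  annotation <- unique(annotation[c("gene", "term", "ontology")])
  empty <- data.frame(term = character(0), ontology = character(0),
                      N = integer(0), n = integer(0), M = integer(0),
                      m = integer(0), p_value = numeric(0),
                      p_bonferroni = numeric(0), enriched = logical(0))
  if (!nrow(annotation)) {
    warning("annotation table is empty after filtering")
    return(empty)
  }
  background <- unique(annotation$gene)
  N <- length(background)
  sel <- intersect(unique(genes), background)
  if (!length(sel)) {
    warning("no screened gene carries an annotation; empty result")
    return(empty)
  }
  n <- length(sel)
  M_tab <- table(annotation$term)
  m_tab <- table(annotation$term[annotation$gene %in% sel])
  tested <- names(m_tab)[m_tab >= 1L]
  M <- as.integer(M_tab[tested])
  m <- as.integer(m_tab[tested])
  p <- hypergeom_enrich_p(N, n, M, m)
  k <- if (divisor == "tested") length(tested) else length(M_tab)
  p_bonf <- pmin(1, p * k)
  onto <- annotation$ontology[match(tested, annotation$term)]
  out <- data.frame(term = tested, ontology = onto, N = N, n = n, M = M,
                    m = m, p_value = p, p_bonferroni = p_bonf,
                    enriched = p_bonf < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_bonferroni, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
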