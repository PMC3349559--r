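#' Adaptor sequences used by the simulator and the default cleaning step
#'
#' A single 3' adaptor is used for simulated adaptor-only reads; cleaning
#' classifies any read that is empty or begins with one of these strings as
#' adaptor-only.
#'
#' @return Character vector of adaptor sequences.
#' @export
tag_adaptors <- function() {
  c("TCGTATGCCGTCTTCTGCTTG")
}

#' Default library labels for a staged five-library design
#'
#' The first library is a non-swelling mutant baseline; the remaining
#' libraries are successive developmental stages of the swelling strain.
#'
#' @param n Number of libraries (>= 3).
#' @return Character vector of labels: `mutant`, `stage1`, `stage2`, ...
#' @export
default_library_names <- function(n = 5) {
  if (!is_count(n) || n < 3) stopf("n_libraries must be an integer >= 3")
  c("mutant", paste0("stage", seq_len(n - 1L)))
}

#' Describe a synthetic DGE experiment
#'
#' Collects and validates the parameters of the synthetic-data generator:
#' reference size, library depth, the fraction and magnitude of true
#' differential expression, and the noise processes (per-base substitution
#' errors, adaptor-only reads, N-containing reads).
#'
#' Defaults describe a staged five-library experiment: 1,000 genes, 200,000
#' raw tags per library, 10% of genes differentially expressed at 8-fold,
#' an Illumina-like per-base error rate of 1e-3, ~1% adaptor-only reads and
#' a trace rate of N-containing reads.
#'
#' @param n_genes Number of unigenes in the reference (>= 2).
#' @param gene_length_range Integer pair, min/max gene length in bp
#'   (within \[60, 20000\]).
#' @param n_libraries Number of libraries (default 5: mutant baseline plus
#'   four stages).
#' @param library_depth Raw tag reads per library.
#' @param de_fraction Proportion of genes truly differentially expressed.
#' @param fold_change_range Positive real pair, lower bound > 1; per-gene
#'   fold changes are drawn log-uniformly from this interval (the default
#'   `c(8, 8)` fixes all changes at 8-fold).
#' @param error_rate Per-base substitution probability.
#' @param adaptor_only_rate Proportion of reads that are adaptor-only.
#' @param n_read_rate Proportion of reads containing an N.
#' @param catg_fraction Fraction of genes guaranteed to carry at least one
#'   taggable CATG site.
#' @param library_names Optional labels; defaults to
#'   [default_library_names()].
#' @param seed Integer seed driving all randomness downstream.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_genes = 1000,
                             gene_length_range = c(200L, 2000L),
                             n_libraries = 5,
                             library_depth = 200000,
                             de_fraction = 0.1,
                             fold_change_range = c(8, 8),
                             error_rate = 0.001,
                             adaptor_only_rate = 0.01,
                             n_read_rate = 2e-05,
                             catg_fraction = 0.95,
                             library_names = NULL,
                             seed = 1) {
  if (!is_count(n_genes) || n_genes < 2) stopf("n_genes must be an integer >= 2")
  if (length(gene_length_range) != 2L || any(is.na(gene_length_range)))
    stopf("gene_length_range must be an integer pair")
  if (gene_length_range[2L] < gene_length_range[1L])
    stopf("gene_length_range is degenerate: max (%d) < min (%d)",
          gene_length_range[2L], gene_length_range[1L])
  if (gene_length_range[1L] < 60 || gene_length_range[2L] > 20000)
    stopf("gene_length_range must lie within [60, 20000]")
  if (!is_count(n_libraries) || n_libraries < 3)
    stopf("n_libraries must be an integer >= 3")
  if (!is_count(library_depth) || library_depth < 1)
    stopf("library_depth must be a positive integer")
  for (nm in c("de_fraction", "error_rate", "adaptor_only_rate",
               "n_read_rate", "catg_fraction")) {
    if (!is_prob(get(nm))) stopf("%s must be a probability in [0, 1]", nm)
  }
  if (adaptor_only_rate + n_read_rate > 1)
    stopf("adaptor_only_rate + n_read_rate must not exceed 1")
  if (length(fold_change_range) != 2L || any(is.na(fold_change_range)))
    stopf("fold_change_range must be a numeric pair")
  if (fold_change_range[1L] <= 1)
    stopf("fold_change_range lower bound must exceed 1")
  if (fold_change_range[2L] < fold_change_range[1L])
    stopf("fold_change_range is degenerate: max < min")
  if (is.null(library_names)) library_names <- default_library_names(n_libraries)
  if (length(library_names) != n_libraries || anyDuplicated(library_names))
    stopf("library_names must be %d unique labels", n_libraries)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("seed must be a single integer")
  structure(list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    n_libraries = as.integer(n_libraries),
    library_depth = as.integer(library_depth),
    de_fraction = de_fraction,
    fold_change_range = as.numeric(fold_change_range),
    error_rate = error_rate,
    adaptor_only_rate = adaptor_only_rate,
    n_read_rate = n_read_rate,
    catg_fraction = catg_fraction,
    library_names = as.character(library_names),
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("Synthetic DGE design:", x$n_genes, "genes,", x$n_libraries,
      "libraries x", x$library_depth, "reads\n")
  cat("  DE fraction", x$de_fraction, "at fold",
      paste(x$fold_change_range, collapse = "-"),
      "| error rate", x$error_rate, "| seed", x$seed, "\n")
  invisible(x)
}

# remove every CATG occurrence; the site is palindromic, so scrubbing the
# stored strand covers both orientations
scrub_catg <- function(s) {
  for (iter in 1:100) {
    g <- gregexpr("CATG", s, fixed = TRUE)[[1L]]
    st <- g[g > 0L]
    if (!length(st)) return(s)
    for (p in st) substr(s, p + 1L, p + 1L) <- "T"
  }
  stopf("failed to remove CATG sites from a simulated sequence")
}

#' Generate a synthetic unigene reference with ground truth
#'
#' Simulates `n_genes` transcript sequences.  A configurable fraction
#' carries at least one CATG site with 17 or more following bases (a site is
#' planted when none arises by chance); the remainder is scrubbed of CATG
#' and therefore untaggable.  Each taggable gene's 3'-most CATG site defines
#' its simulated tag, matching the 3'-anchored NlaIII/MmeI chemistry.
#' Stored unigene orientation is randomised (as for de novo assemblies), so
#' roughly half of the truth tags sit on the minus strand of the stored
#' sequence.
#'
#' Baseline abundances are drawn log-normal (meanlog 0, sdlog 1.5) and
#' normalised to sum to one.  A `de_fraction` subset of taggable genes
#' receives a fold change `f` (log-uniform in `fold_change_range`, random
#' direction) applied as a monotone trajectory over the stage libraries:
#' multipliers 1, f^(1/3), f^(2/3), f for stages 1-4 and 1 in the mutant
#' baseline.
#'
#' @param design A [synthetic_design()].
#' @return An object of class `sim_reference`: list with `sequences`
#'   (named `DNAStringSet`), `truth` (data frame: gene, length, abundance,
#'   taggable, tag, strand, tag_pos, is_de, fold, direction, and one
#'   `mult_<library>` column per library), `multipliers` (gene x library
#'   matrix) and the echoed `design`.
#' @export
make_reference <- function(design) {
  if (!inherits(design, "synthetic_design"))
    stopf("design must be a synthetic_design object")
  set.seed(design$seed)
  n <- design$n_genes
  gene <- sprintf("gene_%0*d", nchar(as.character(n)), seq_len(n))
  len <- sample(seq(design$gene_length_range[1L], design$gene_length_range[2L]),
                n, replace = TRUE)
  taggable <- logical(n)
  taggable[sample.int(n, round(design$catg_fraction * n))] <- TRUE
  tx <- vapply(len, random_seq, character(1))
  for (i in which(!taggable)) tx[i] <- scrub_catg(tx[i])
  site <- rep(NA_integer_, n)
  for (i in which(taggable)) {
    s <- catg_sites(tx[i])
    if (!length(s)) {
      p <- sample.int(len[i] - 20L, 1L)
      substr(tx[i], p, p + 3L) <- "CATG"
      s <- catg_sites(tx[i])
    }
    site[i] <- max(s) # 3'-most site generates the tag
  }
  tag <- rep(NA_character_, n)
  tag[taggable] <- substr(tx[taggable], site[taggable], site[taggable] + 20L)
  flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
  stored <- tx
  stored[flip] <- revcomp(tx[flip])
  strand <- ifelse(flip, "-", "+")
  strand[!taggable] <- NA_character_
  abundance <- rlnorm(n, meanlog = 0, sdlog = 1.5)
  abundance <- abundance / sum(abundance)

  n_de <- round(design$de_fraction * n)
  tg_idx <- which(taggable)
  de_idx <- tg_idx[sample.int(length(tg_idx), min(n_de, length(tg_idx)))]
  is_de <- seq_len(n) %in% de_idx
  direction <- integer(n)
  direction[de_idx] <- sample(c(1L, -1L), length(de_idx), replace = TRUE)
  fold <- rep(1, n)
  fold[de_idx] <- exp(runif(length(de_idx),
                            log(design$fold_change_range[1L]),
                            log(design$fold_change_range[2L])))
  # multiplier trajectory: baseline mutant at 1x, stages at f^(0), f^(1/3), ...
  expo <- c(0, seq(0, 1, length.out = design$n_libraries - 1L))
  mult <- matrix(1, n, design$n_libraries,
                 dimnames = list(gene, design$library_names))
  for (j in seq_len(design$n_libraries)) {
    mult[, j] <- fold^(direction * expo[j])
  }
  truth <- data.frame(gene = gene, length = len, abundance = abundance,
                      taggable = taggable, tag = tag, strand = strand,
                      tag_pos = site, is_de = is_de, fold = fold,
                      direction = direction, stringsAsFactors = FALSE)
  mult_df <- as.data.frame(mult)
  names(mult_df) <- paste0("mult_", design$library_names)
  truth <- cbind(truth, mult_df)
  rownames(truth) <- NULL
  sequences <- Biostrings::DNAStringSet(stored)
  names(sequences) <- gene
  structure(list(sequences = sequences, truth = truth, multipliers = mult,
                 design = design), class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("Synthetic unigene reference:", length(x$sequences), "genes (",
      sum(x$truth$taggable), "taggable,", sum(x$truth$is_de), "DE )\n")
  invisible(x)
}

resolve_library <- function(library, design) {
  if (is.character(library)) {
    idx <- match(library, design$library_names)
    if (is.na(idx)) stopf("unknown library label '%s'", library)
  } else {
    idx <- as.integer(library)
    if (is.na(idx) || idx < 1L || idx > design$n_libraries)
      stopf("library index out of range: %s (design has %d libraries)",
            library, design$n_libraries)
  }
  idx
}

#' Simulate one raw tag library
#'
#' Reads are drawn per category (tag, adaptor-only, N-containing) and tag
#' reads multinomially over taggable genes with probability proportional to
#' abundance times the library's fold multiplier.  Each tag read is the
#' gene's 3'-most CATG+17 tag subjected to iid per-base substitution at
#' `error_rate`.  The read count equals `library_depth` exactly, and true
#' per-gene sampled counts (before error injection) are returned alongside.
#'
#' @param reference A `sim_reference` from [make_reference()].
#' @param library Library index (1-based) or label.
#' @param design Design to simulate under; defaults to the one stored in
#'   `reference`.
#' @return An object of class `sim_library`: list with `library` (label),
#'   `index`, `reads` (character vector, shuffled), `origin` (per-read gene
#'   id or `"adaptor_only"` / `"containing_N"`), `true_counts` (named
#'   integer vector over all genes) and `depth`.
#' @export
simulate_library <- function(reference, library, design = reference$design) {
  if (!inherits(reference, "sim_reference"))
    stopf("reference must come from make_reference()")
  idx <- resolve_library(library, design)
  set.seed(design$seed + 7919L * idx)
  truth <- reference$truth
  tg <- which(truth$taggable)
  if (!length(tg)) stopf("reference contains no taggable gene")
  p <- truth$abundance[tg] * reference$multipliers[tg, idx]
  p <- p / sum(p)
  depth <- design$library_depth
  a <- design$adaptor_only_rate
  nr <- design$n_read_rate
  cat_counts <- as.vector(rmultinom(1L, depth, c(1 - a - nr, a, nr)))
  n_tag <- cat_counts[1L]; n_ad <- cat_counts[2L]; n_nr <- cat_counts[3L]
  gc <- as.vector(rmultinom(1L, n_tag, p))
  tag_reads <- rep(truth$tag[tg], gc)
  origin <- rep(truth$gene[tg], gc)
  if (design$error_rate > 0 && n_tag > 0L) {
    nerr <- rbinom(n_tag, 21L, design$error_rate)
    bases <- c("A", "C", "G", "T")
    for (i in which(nerr > 0L)) {
      pos <- sample.int(21L, nerr[i])
      for (pp in pos) {
        old <- substr(tag_reads[i], pp, pp)
        substr(tag_reads[i], pp, pp) <- sample(setdiff(bases, old), 1L)
      }
    }
  }
  ad_reads <- rep(tag_adaptors()[1L], n_ad)
  nr_reads <- character(0)
  if (n_nr > 0L) {
    src <- sample.int(length(tg), n_nr, replace = TRUE, prob = p)
    nr_reads <- truth$tag[tg][src]
    pos <- sample.int(21L, n_nr, replace = TRUE)
    for (i in seq_len(n_nr)) substr(nr_reads[i], pos[i], pos[i]) <- "N"
  }
  reads <- c(tag_reads, ad_reads, nr_reads)
  origin <- c(origin, rep("adaptor_only", n_ad), rep("containing_N", n_nr))
  perm <- sample.int(length(reads))
  true_counts <- setNames(integer(nrow(truth)), truth$gene)
  true_counts[tg] <- gc
  structure(list(library = design$library_names[idx], index = idx,
                 reads = reads[perm], origin = origin[perm],
                 true_counts = true_counts, depth = depth),
            class = "sim_library")
}

#' Simulate a full staged experiment
#'
#' Runs [make_reference()] once and [simulate_library()] for every library
#' in the design.
#'
#' @param design A [synthetic_design()].
#' @return List of class `sim_experiment` with `reference` and `libraries`
#'   (named list of `sim_library`).
#' @export
simulate_experiment <- function(design) {
  reference <- make_reference(design)
  libraries <- lapply(seq_len(design$n_libraries), function(i) {
    simulate_library(reference, i, design)
  })
  names(libraries) <- design$library_names
  structure(list(reference = reference, libraries = libraries),
            class = "sim_experiment")
}

#' Simulate a gene-to-term annotation table
#'
#' Assigns a fraction of genes one to three GO/KO-like terms.  Truly DE
#' genes are biased into the first `de_terms` terms so that enrichment of a
#' DE-derived gene set has a planted positive signal.
#'
#' @param reference A `sim_reference`.
#' @param n_terms Number of distinct terms.
#' @param annotated_fraction Fraction of genes carrying any annotation.
#' @param de_terms Number of terms attracting DE genes.
#' @param de_term_bias Probability a DE gene's first term is a DE-attracting
#'   term.
#' @param seed Seed; defaults to an offset of the design seed.
#' @return Data frame with columns `gene`, `term`, `ontology`.
#' @export
simulate_annotation <- function(reference, n_terms = 30,
                                annotated_fraction = 0.8,
                                de_terms = 2, de_term_bias = 0.6,
                                seed = reference$design$seed + 104729L) {
  if (!inherits(reference, "sim_reference"))
    stopf("reference must come from make_reference()")
  if (n_terms < de_terms + 1) stopf("n_terms must exceed de_terms")
  set.seed(seed)
  truth <- reference$truth
  n <- nrow(truth)
  term_ids <- sprintf("TERM%03d", seq_len(n_terms))
  ontology <- rep(c("GO", "KO"), length.out = n_terms)
  ann_genes <- sort(sample.int(n, round(annotated_fraction * n)))
  rows <- vector("list", length(ann_genes))
  for (k in seq_along(ann_genes)) {
    i <- ann_genes[k]
    n_assign <- sample.int(3L, 1L)
    if (truth$is_de[i] && runif(1) < de_term_bias) {
      first <- sample.int(de_terms, 1L)
      extra <- sample((de_terms + 1L):n_terms, n_assign - 1L)
      terms <- term_ids[c(first, extra)]
    } else {
      terms <- term_ids[sample((de_terms + 1L):n_terms, n_assign)]
    }
    rows[[k]] <- data.frame(gene = truth$gene[i], term = terms,
                            ontology = ontology[match(terms, term_ids)],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ground-truth differential-expression flags per comparison
#'
#' A gene is truly differentially expressed in a comparison when its fold
#' multipliers differ between the case and control libraries.
#'
#' @param reference A `sim_reference` (or its truth/multiplier pair).
#' @param design A [comparison_design()]; defaults to the six staged
#'   comparisons over the reference's libraries.
#' @return Logical gene x comparison matrix.
#' @export
true_de_flags <- function(reference, design = NULL) {
  mult <- reference$multipliers
  if (is.null(design)) design <- default_comparisons(colnames(mult))
  flags <- sapply(seq_len(nrow(design)), function(r) {
    mult[, design$case[r]] != mult[, design$control[r]]
  })
  colnames(flags) <- design$comparison
  rownames(flags) <- rownames(mult)
  flags
}

write_fastq <- function(reads, path, prefix = "read") {
  n <- length(reads)
  ids <- sprintf("@%s_%d", prefix, seq_len(n))
  qual <- strrep("I", nchar(reads))
  out <- as.vector(rbind(ids, reads, "+", qual))
  writeLines(out, path)
  invisible(path)
}

read_counts_table <- function(reads) {
  tab <- table(reads)
  data.frame(tag = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)[order(-as.integer(tab), names(tab)), ,
                                       drop = FALSE]
}

#' Write a simulated experiment to disk
#'
#' Emits the reference FASTA, per-library FASTQ (constant quality `I`) and
#' tag/count TSV, a truth table with per-comparison DE flags, and a YAML
#' echo of the design.
#'
#' @param experiment A `sim_experiment`.
#' @param dir Output directory (created if needed).
#' @param annotation Optional annotation data frame, written as
#'   `annotation.tsv`.
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(experiment, dir, annotation = NULL) {
  if (!inherits(experiment, "sim_experiment"))
    stopf("experiment must come from simulate_experiment()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- experiment$reference
  paths <- character(0)
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(ref$sequences, fa)
  paths <- c(paths, fa)
  flags <- as.data.frame(true_de_flags(ref))
  names(flags) <- paste0("de_", names(flags))
  truth <- cbind(ref$truth, flags)
  tp <- file.path(dir, "truth.tsv")
  write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, tp)
  for (lib in experiment$libraries) {
    fq <- file.path(dir, paste0(lib$library, ".fq"))
    write_fastq(lib$reads, fq, prefix = lib$library)
    tsv <- file.path(dir, paste0(lib$library, ".tsv"))
    write.table(read_counts_table(lib$reads), tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, fq, tsv)
  }
  yml <- file.path(dir, "design.yaml")
  yaml::write_yaml(unclass(ref$design), yml)
  paths <- c(paths, yml)
  invisible(paths)
}
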