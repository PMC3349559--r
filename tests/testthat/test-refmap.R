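test_that("index extracts every anchored 21-mer and flags ambiguity", {
  # single valid site on the plus strand
  idx <- build_tag_index(seqs_with_tags(g1 = "AACATGACGTACGTACGTACGTA"))
  expect_identical(nrow(idx$entries), 1L)
  expect_identical(idx$entries$tag, "CATGACGTACGTACGTACGTA")
  expect_identical(idx$entries$strand, "+")
  expect_identical(idx$entries$start, 3L)

  # no CATG on either strand: untaggable gene contributes nothing
  idx0 <- build_tag_index(seqs_with_tags(g1 = strrep("AC", 40)))
  expect_identical(nrow(idx0$entries), 0L)
  expect_identical(unname(idx0$gene_lengths), 80L)

  # shared tag across two genes is ambiguous
  shared <- paste0("CATG", strrep("A", 17))
  idx2 <- build_tag_index(seqs_with_tags(
    g1 = paste0("TT", shared, "TT"), g2 = paste0("GG", shared)))
  expect_identical(idx2$ambiguous, shared)

  expect_error(build_tag_index(Biostrings::DNAStringSet(
    setNames(c("CATGAAAAAAAAAAAAAAAAA", "CATGCCCCCCCCCCCCCCCCC"),
             c("dup", "dup")))), "dup")
})

test_that("minus-strand sites are indexed with correct plus coordinates", {
  tag <- "CATGACGTACGTACGTACGTA"
  gene <- revcomp(tag)  # the stored gene is the reverse complement
  idx <- build_tag_index(seqs_with_tags(g1 = gene))
  minus <- idx$entries[idx$entries$strand == "-", ]
  expect_identical(minus$tag, tag)
  expect_identical(minus$start_plus, 1L)
  expect_identical(minus$end_plus, 21L)
  # verbatim substring of the reverse complement of the stored gene
  expect_identical(substr(revcomp(gene), minus$start, minus$start + 20L), tag)
})

test_that("every truth tag-generating site appears in the index", {
  ref <- make_reference(small_design(seed = 8))
  idx <- build_tag_index(ref)
  truth <- ref$truth[ref$truth$taggable, ]
  key_idx <- paste(idx$entries$gene, idx$entries$strand, idx$entries$tag)
  key_truth <- paste(truth$gene, truth$strand, truth$tag)
  expect_true(all(key_truth %in% key_idx))
  # the truth site is the 3'-most on its strand
  m <- match(key_truth, key_idx)
  expect_true(all(idx$entries$site_rank[m] == 1L))
})

test_that("mapping applies the minimal-distance and multi-gene tie rules", {
  tagA <- paste0("CATG", strrep("A", 17))
  tagB <- paste0("CATG", strrep("A", 15), "CC")
  idx <- build_tag_index(seqs_with_tags(
    geneA = paste0("TT", tagA, "T"), geneB = paste0("TT", tagB, "T")))

  mk <- function(tags, counts) data.frame(tag = tags, count = counts)

  # exact unambiguous hit: perfect, unique, counted
  m <- map_tags(mk(tagA, 5L), idx)
  expect_identical(unname(m$counts["geneA"]), 5L)
  expect_identical(unname(m$ledger[["perfect_match"]]), 5L)
  expect_identical(unname(m$ledger[["unique_match"]]), 5L)

  # Hamming distance 2 from everything with max_mismatch = 1: unmapped
  far <- paste0("CATG", strrep("A", 15), "GG")  # d2 from A, d2 from B
  m2 <- map_tags(mk(far, 3L), idx, max_mismatch = 1)
  expect_identical(unname(m2$ledger[["unmapped"]]), 3L)
  expect_identical(sum(m2$counts), 0L)

  # distance 1 from tags of two different genes: multi-position, no gene
  tie <- paste0("CATG", strrep("A", 15), "AC")  # d1 from A and d1 from B
  expect_identical(hamming(tie, tagA), 1L)
  expect_identical(hamming(tie, tagB), 1L)
  m3 <- map_tags(mk(tie, 4L), idx)
  expect_identical(unname(m3$ledger[["multi_position"]]), 4L)
  expect_identical(sum(m3$counts), 0L)

  # a perfect hit dominates a mismatch hit to another gene
  m4 <- map_tags(mk(tagA, 2L), idx, max_mismatch = 2)
  expect_identical(unname(m4$counts["geneA"]), 2L)
  expect_identical(unname(m4$ledger[["perfect_match"]]), 2L)
})

test_that("ledger identities hold and mapping is monotone in max_mismatch", {
  d <- small_design(seed = 4, error_rate = 0.01)
  ref <- make_reference(d)
  idx <- build_tag_index(ref)
  ct <- filter_raw_tags(simulate_library(ref, 3))
  prev <- -1L
  for (mm in 0:2) {
    m <- map_tags(ct, idx, max_mismatch = mm)
    L <- m$ledger
    expect_identical(unname(L[["total_mapped"]]),
                     unname(L[["perfect_match"]] + L[["mismatch_match"]]))
    expect_identical(unname(L[["total_mapped"]]),
                     unname(L[["unique_match"]] + L[["multi_position"]]))
    expect_identical(unname(L[["total_clean"]]),
                     unname(L[["total_mapped"]] + L[["unmapped"]]))
    expect_identical(unname(L[["total_clean"]]),
                     unname(ct$ledger[["clean"]]))
    expect_gte(L[["total_mapped"]], prev)
    prev <- L[["total_mapped"]]
  }
})

test_that("zero-noise mapped counts recover true counts for unambiguous genes", {
  d <- noiseless_design(n_genes = 200, library_depth = 20000, seed = 6)
  ref <- make_reference(d)
  idx <- build_tag_index(ref)
  lib <- simulate_library(ref, 1)
  m <- map_tags(filter_raw_tags(lib, min_copy = 1), idx)
  amb_genes <- unique(idx$entries$gene[idx$entries$tag %in% idx$ambiguous])
  ok <- setdiff(names(lib$true_counts), amb_genes)
  expect_identical(m$counts[ok], lib$true_counts[ok])
})

test_that("coverage is the union of tag footprints over gene length", {
  tag <- paste0("CATG", strrep("G", 17))
  gene <- paste0(strrep("T", 10), tag, strrep("T", 69))  # length 100, site at 11
  idx <- build_tag_index(seqs_with_tags(g = gene))
  m <- map_tags(data.frame(tag = tag, count = 3L), idx)
  cov <- coverage_profile(m)
  expect_equal(cov$genes$coverage[cov$genes$gene == "g"], 0.21)

  # no mapped tags: coverage 0
  m0 <- map_tags(data.frame(tag = character(0), count = integer(0)), idx)
  expect_equal(coverage_profile(m0)$genes$coverage, 0)

  # overlapping footprints: brute-force union oracle
  ref <- make_reference(small_design(seed = 12))
  idx2 <- build_tag_index(ref)
  ct <- filter_raw_tags(simulate_library(ref, 2))
  m2 <- map_tags(ct, idx2)
  cov2 <- coverage_profile(m2)
  for (g in head(unique(m2$placements$gene), 15)) {
    pl <- m2$placements[m2$placements$gene == g, ]
    len <- idx2$gene_lengths[[g]]
    mask <- logical(len)
    for (r in seq_len(nrow(pl))) {
      mask[pl$start[r]:min(pl$end[r], len)] <- TRUE
    }
    expect_equal(cov2$genes$coverage[cov2$genes$gene == g], sum(mask) / len)
  }
})

test_that("two overlapping placements covering 30 of 60 bases give one half", {
  # 21-bp footprints at starts 1 and 10 cover bases 1..30 of a 60 bp gene
  tagA <- paste0("CATG", strrep("A", 5), "CATG", strrep("A", 8))
  idx <- build_tag_index(seqs_with_tags(
    g = paste0(tagA, strrep("A", 9), strrep("T", 30))))
  # both sites of gene g share no tags with other genes; map both site tags
  tags <- unique(idx$entries$tag[idx$entries$strand == "+"])
  m <- map_tags(data.frame(tag = tags, count = 2L), idx)
  expect_equal(coverage_profile(m)$genes$coverage, 0.5)
})
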