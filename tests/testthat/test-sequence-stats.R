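test_that("linker extraction follows 1-based inclusive domain coordinates", {
  parent <- make_synthetic_parent()
  expect_identical(nchar(parent), 364L)
  rec <- extract_linker(parent, synthetic_domain_annotations())
  expect_identical(rec$start_res, 229L)
  expect_identical(rec$end_res, 262L)
  expect_identical(nchar(rec$sequence), 34L)
  expect_identical(rec$sequence, SYN_WT_LINKER)

  # direct index arithmetic on a 12-mer
  ann <- data.frame(parent_id = "p", domain_name = c("d1", "d2"),
                    start_res = c(1L, 10L), end_res = c(5L, 12L))
  rec2 <- extract_linker(poly("A", 12), ann)
  expect_identical(c(rec2$start_res, rec2$end_res), c(6L, 9L))
  expect_identical(nchar(rec2$sequence), 4L)
})

test_that("degenerate architectures are rejected with clear errors", {
  ann_adj <- data.frame(parent_id = "p", domain_name = c("d1", "d2"),
                        start_res = c(1L, 11L), end_res = c(10L, 20L))
  expect_error(extract_linker(poly("A", 20), ann_adj), "empty linker")
  ann_ovl <- ann_adj; ann_ovl$start_res[2] <- 8L
  expect_error(extract_linker(poly("A", 20), ann_ovl), "overlap")
  expect_error(extract_linker(poly("A", 20), ann_adj[1, ]),
               "unsupported architecture")
  expect_error(extract_linker(poly("A", 20), rbind(ann_adj, ann_adj[1, ])),
               "unsupported architecture")
})

test_that("composition descriptors match hand counts", {
  cs <- compute_composition("DKPE")
  expect_equal(cs$ncpr, -0.25)
  expect_equal(cs$fraction_expanding, 1.0)
  expect_equal(cs$fraction_proline, 0.25)

  # a charge-free 34-mer: all descriptors zero
  cs0 <- compute_composition(paste0(poly("S", 14), poly("G", 12),
                                    poly("N", 8)))
  expect_equal(cs0$ncpr, 0)
  expect_equal(cs0$fraction_expanding, 0)
  expect_equal(cs0$fraction_proline, 0)
  expect_equal(sum(cs0$aa_frequencies), 1, tolerance = 1e-12)

  expect_error(compute_composition("ACDX"), "X")
  expect_error(compute_composition(""), "non-empty")
})

test_that("composition is permutation invariant and identities hold", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(20:60, 1)
    s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                      replace = TRUE), collapse = "")
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    a <- compute_composition(s); b <- compute_composition(perm)
    expect_equal(a$ncpr, b$ncpr)
    expect_equal(a$aa_frequencies, b$aa_frequencies)
    # expanding = proline + charged-residue fraction, exactly
    charged <- sum(a$aa_frequencies[c("D", "E", "K", "R")])
    expect_equal(a$fraction_expanding, a$fraction_proline + charged,
                 tolerance = 1e-12)
  }
})

test_that("extraction composes with composition on concatenated domains", {
  linker <- "GTPGSDTKPEGT"
  d1 <- poly("W", 30); d2 <- poly("F", 25)
  parent <- paste0(d1, linker, d2)
  ann <- data.frame(parent_id = "p", domain_name = c("d1", "d2"),
                    start_res = c(1L, 43L), end_res = c(30L, 67L))
  rec <- extract_linker(parent, ann)
  expect_identical(rec$sequence, linker)
  expect_equal(compute_composition(rec)$ncpr,
               compute_composition(linker)$ncpr)
})

test_that("FASTA and domain-TSV round trips preserve the survey inputs", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(p1 = make_synthetic_parent(), p2 = poly("A", 50))
  write_fasta_sequences(seqs, fa)
  expect_identical(read_fasta_sequences(fa), seqs)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  ann <- synthetic_domain_annotations("p1")
  write.table(ann, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_domain_annotations(tsv), ann)
})

test_that("survey reports valid parents and skips bad architectures", {
  seqs <- c(a = make_synthetic_parent(), b = poly("A", 20),
            c = poly("G", 30), d = poly("T", 40))
  ann <- rbind(
    synthetic_domain_annotations("a"),
    data.frame(parent_id = "b", domain_name = c("x", "y"),
               start_res = c(1L, 10L), end_res = c(5L, 20L)),
    data.frame(parent_id = "c", domain_name = c("x", "y", "z"),
               start_res = c(1L, 10L, 20L), end_res = c(5L, 15L, 30L)),
    data.frame(parent_id = "d", domain_name = c("x", "y"),
               start_res = c(1L, 30L), end_res = c(10L, 40L)))
  expect_warning(res <- survey_linkers(seqs, ann), "skipped")
  expect_identical(sort(res$parent_id), c("a", "b", "d"))
  expect_identical(attr(res, "skipped"), "c")
  expect_identical(res$n_residues[res$parent_id == "a"], 34L)

  # empty inputs give an empty table, not an error
  empty <- survey_linkers(character(), ann[0, ])
  expect_identical(nrow(empty), 0L)
})
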