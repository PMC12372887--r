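toy_msa <- function(seqs, ids = sprintf("s%d", seq_along(seqs))) {
  f <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), f)
  read_msa(f)
}

test_that("aligned FASTA reading validates and normalizes gaps", {
  m <- toy_msa(c("ACDEF", "ACDEF"))
  expect_equal(ncol(m$seqs), 5)
  expect_error(toy_msa("ACDEF"), "at least 2")
  expect_error(toy_msa(c("ACDEF", "ACD")), "s2")
  expect_error(toy_msa(c("AC", "AC"), ids = c("a", "a")), "duplicate")
  # '.' and '-' both read as gaps
  m2 <- toy_msa(c("A.C-E", "AACEE"))
  expect_equal(unname(m2$seqs[1, c(2, 4)]), c("-", "-"))
  # write/read round trip of a synthetic alignment
  syn <- make_msa(n_seqs = 10, n_conserved = 4, n_variable = 4,
                  n_intermediate = 4, seed = 3)
  f <- tempfile(fileext = ".fasta")
  write_msa(syn$msa, f)
  back <- read_msa(f)
  expect_identical(back$seqs, syn$msa$seqs)
})

test_that("Henikoff weights are symmetric, normalized, and favor outliers", {
  m <- toy_msa(rep("ACDEF", 4))
  expect_equal(unname(sequence_weights(m)), rep(0.25, 4))

  # one divergent + three identical: the divergent row dominates, and the
  # values match a literal re-computation
  m2 <- toy_msa(c("ACDEF", "ACDEF", "ACDEF", "WYWYW"))
  w <- sequence_weights(m2)
  expect_equal(which.max(w), 4L, ignore_attr = TRUE)
  expect_equal(unname(w), oracle_henikoff(m2$seqs), tolerance = 1e-12)

  set.seed(5)
  for (rep in 1:5) {
    seqs <- replicate(6, paste0(sample(c("A", "R", "N", "D", "-"), 12,
                                       replace = TRUE), collapse = ""))
    m3 <- toy_msa(seqs)
    w3 <- sequence_weights(m3)
    expect_equal(sum(w3), 1, tolerance = 1e-12)
    expect_true(all(w3 > 0))
  }
})

test_that("column scores equal a direct-summation JSD oracle", {
  set.seed(9)
  seqs <- replicate(8, paste0(sample(c("A","R","N","D","E","G","-"), 30,
                                     replace = TRUE), collapse = ""))
  m <- toy_msa(seqs)
  w <- sequence_weights(m)
  sc <- column_scores(m, w)
  bg <- robinson_frequencies()
  for (j in seq_len(ncol(m$seqs))) {
    col <- m$seqs[, j]
    keep <- col %in% names(bg)
    if (!any(keep)) {
      expect_equal(sc[j], 0)
      next
    }
    p <- setNames(numeric(20), names(bg))
    for (i in which(keep)) p[col[i]] <- p[col[i]] + w[i]
    p <- p / sum(p)
    expect_equal(sc[j], unname(oracle_jsd(p, bg) * sum(w[keep])),
                 tolerance = 1e-10)
  }
})

test_that("score extremes behave as conservation demands", {
  # single-residue column scores highest among full columns; a column
  # distributed exactly like the background scores 0
  bg <- robinson_frequencies()
  m <- toy_msa(c("AA", "AR", "AN", "AD", "AC"))
  sc <- column_scores(m, background = bg)
  expect_gt(sc[1], sc[2])
  # the divergence of a distribution from itself is zero, so a column whose
  # weighted composition equals the background scores zero
  expect_equal(kinconform:::js_divergence(bg, bg), 0, tolerance = 1e-12)

  # duplicate sequences leave scores essentially unchanged
  m1 <- toy_msa(c("ACDEF", "ARDEF", "ACNEF"))
  m2 <- toy_msa(c("ACDEF", "ACDEF", "ACDEF", "ARDEF", "ARDEF", "ARDEF",
                  "ACNEF", "ACNEF", "ACNEF"))
  s1 <- column_scores(m1)
  s2 <- column_scores(m2)
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("grading is monotone, bounded 1-9, with stated tie rules", {
  expect_equal(grade_scores(rep(0.3, 12)), rep(5L, 12))
  expect_equal(grade_scores(seq(0.1, 0.9, length.out = 9)), 1:9)
  set.seed(13)
  sc <- runif(200)
  g <- grade_scores(sc)
  expect_true(all(g >= 1 & g <= 9))
  # sort-based oracle: equal-count rank bins, grade 9 for the top bin
  expect_equal(g, as.integer(floor((rank(sc) - 1) * 9 / length(sc)) + 1))
  # a higher score never maps to a lower grade
  o <- order(sc)
  expect_true(all(diff(g[o]) >= 0))
})

test_that("confidence flags catch sparse and unstable columns", {
  # a column with 5 non-gap residues in a 50-sequence alignment is flagged
  base <- matrix("A", nrow = 50, ncol = 6)
  base[6:50, 3] <- "-"
  base[, 5] <- rep(c("A","R","N","D","E"), 10)
  ids <- sprintf("s%02d", 1:50)
  rownames(base) <- ids
  m <- structure(list(ids = ids, seqs = base), class = "kinase_msa")
  fl <- flag_confidence(m, n_bootstrap = 50, seed = 4)
  expect_true(fl[3])

  # perfectly conserved columns of identical sequences are never flagged
  m2 <- toy_msa(rep("ACDEFGHIK", 50))
  fl2 <- flag_confidence(m2, n_bootstrap = 50, seed = 4)
  expect_false(any(fl2))

  expect_error(flag_confidence(m2, n_bootstrap = 10, seed = 1),
               "at least 50")
  expect_error(flag_confidence(m2, n_bootstrap = 50), "seed")
})

test_that("bootstrap flag decisions are stable at 10x replicates", {
  # planted ambiguous column: two residues at 50/50 in 8 sequences,
  # alongside a spread of stable columns
  set.seed(21)
  n <- 8
  stable <- sapply(1:10, function(j) rep(sample(c("A","R","N","D"), 1), n))
  ambig <- rep(c("W", "C"), 4)
  seqs <- cbind(stable, ambig)
  ids <- sprintf("s%d", 1:n)
  rownames(seqs) <- ids
  m <- structure(list(ids = ids, seqs = seqs), class = "kinase_msa")
  f_lo <- flag_confidence(m, n_bootstrap = 200, seed = 8)
  f_hi <- flag_confidence(m, n_bootstrap = 2000, seed = 8)
  expect_identical(f_lo[11], f_hi[11])
})

test_that("pairwise identity counts mutually non-gap matches", {
  m <- toy_msa(c("ACDEFGHIKL", "ACDEFGHIKV", "AC-EFGHIKL"))
  pid <- pairwise_identity(m, "s1")
  expect_equal(pid$identity[pid$query_id == "s1"], 100)
  expect_equal(pid$identity[pid$query_id == "s2"], 90)
  expect_equal(pid$n_aligned[pid$query_id == "s3"], 9)
  expect_error(pairwise_identity(m, "nope"), "not in the alignment")

  # random alignments against the counting oracle; symmetry in the pair
  set.seed(31)
  for (rep in 1:5) {
    seqs <- replicate(4, paste0(sample(c("A","R","N","D","-"), 25,
                                       replace = TRUE), collapse = ""))
    mr <- toy_msa(seqs)
    pid <- pairwise_identity(mr, "s2")
    for (k in 1:4) {
      expect_equal(pid$identity[k],
                   oracle_identity(mr$seqs["s2", ], mr$seqs[pid$query_id[k], ]))
    }
    # symmetry: reference s3 vs query s2 equals reference s2 vs query s3
    pid2 <- pairwise_identity(mr, "s3")
    expect_equal(pid$identity[pid$query_id == "s3"],
                 pid2$identity[pid2$query_id == "s2"])
  }
})

test_that("column-to-residue mapping skips reference gaps", {
  m <- toy_msa(c("ABCDE", "ABCDE"))
  expect_equal(map_to_reference(m, "s1", 6), 6:10)
  m2 <- toy_msa(c("A-CD", "AACD"))
  expect_equal(map_to_reference(m2, "s1", 1), c(1L, NA, 2L, 3L))
  set.seed(17)
  for (rep in 1:5) {
    seqs <- replicate(2, paste0(sample(c("A", "C", "-"), 30, replace = TRUE),
                                collapse = ""))
    mr <- toy_msa(seqs)
    expect_equal(map_to_reference(mr, "s1", 42),
                 oracle_map(mr$seqs["s1", ], 42))
  }
})

test_that("planted conserved and variable columns separate into extreme grades", {
  syn <- make_msa(n_seqs = 50, n_conserved = 20, n_variable = 20,
                  n_intermediate = 50, seed = 101)
  prof <- conservation_profile(syn$msa, reference_id = syn$msa$ids[1],
                               first_residue_number = 6, seed = 101,
                               n_bootstrap = 50)
  expect_true(all(prof$grade[syn$labels == "conserved"] >= 8))
  expect_true(all(prof$grade[syn$labels == "variable"] <= 2))
  expect_equal(attr(prof, "method_tag"), "jsd-henikoff-v1")
  # mapped residue numbers strictly increase along mapped columns
  rn <- prof$residue_number[!is.na(prof$residue_number)]
  expect_true(all(diff(rn) > 0))
})
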