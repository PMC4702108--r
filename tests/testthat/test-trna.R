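test_that("anticodon decoding follows the invertebrate mt code for all 22 families", {
  for (fam in names(mitoarch:::MT_ANTICODONS)) {
    dec <- decode_anticodon(mitoarch:::MT_ANTICODONS[[fam]])
    expect_identical(dec$family, fam)
    expect_true(dec$known)
  }
  expect_identical(decode_anticodon("CAT")$aa, "M")
  expect_identical(decode_anticodon("TCA")$aa, "W") # TGA codon = Trp in mt code
  expect_identical(decode_anticodon("gta")$family, "trnY")
})

test_that("anticodon location ranks a well-supported loop first and can come up empty", {
  tr <- generate_trna("trnM", seed = 5)
  cand <- locate_anticodon(tr$sequence)
  expect_gt(nrow(cand), 0)
  expect_identical(cand$anticodon[1], "CAT")
  expect_identical(cand$anticodon_start[1], tr$anticodon_start)
  expect_identical(decode_anticodon(cand$anticodon[1])$aa, "M")
  # expected anticodon promotes matching candidates
  cand2 <- locate_anticodon(tr$sequence, expected = "CAT")
  expect_true(cand2$matches_expected[1])
  # homopolymer has no paired loop at all
  expect_identical(nrow(locate_anticodon(strrep("A", 60))), 0L)
})

test_that("folding recovers designed architectures and respects size bounds", {
  cases <- list(
    list(spec = list(family = "trnM"), class = "cloverleaf"),
    list(spec = list(family = "trnC", t_arm = FALSE), class = "T-armless"),
    list(spec = list(family = "trnS2", d_arm = FALSE), class = "D-armless"),
    list(spec = list(family = "trnY", d_arm = FALSE, t_arm = FALSE,
                     replacement_len = 8), class = "armless"))
  for (cs in cases) {
    tr <- do.call(generate_trna, c(cs$spec, list(seed = 9)))
    st <- fold_trna(tr$sequence, tr$anticodon_start)
    expect_identical(classify_trna(st), cs$class)
    expect_identical(st$family, cs$spec$family)
  }
  # the armless case realizes the minimal observed size class (47 nt)
  tr47 <- generate_trna("trnA", d_arm = FALSE, t_arm = FALSE,
                        replacement_len = 8, seed = 1)
  expect_identical(nchar(tr47$sequence), 47L)
  expect_identical(classify_trna(fold_trna(tr47$sequence, tr47$anticodon_start)),
                   "armless")
  expect_error(fold_trna(strrep("ACGT", 9), 10), "\\[40, 100\\]")
  expect_error(locate_anticodon(strrep("ACGT", 30)), "\\[40, 100\\]")
})

test_that("classification is a pure function of arm presence", {
  tr <- generate_trna("trnM", seed = 2)
  st <- fold_trna(tr$sequence, tr$anticodon_start)
  st$d_arm$present <- FALSE
  expect_identical(classify_trna(st), "D-armless")
  st$t_arm$present <- FALSE
  expect_identical(classify_trna(st), "armless")
  st$d_arm$present <- TRUE
  expect_identical(classify_trna(st), "T-armless")
})

test_that("folding is deterministic and never pairs a base twice or outside WC/GU", {
  set.seed(505)
  ok_pair <- function(s, i, j) {
    p <- paste0(substr(s, i, i), substr(s, j, j))
    p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  for (i in 1:30) {
    fam <- sample(names(mitoarch:::MT_ANTICODONS), 1)
    tr <- generate_trna(fam, d_arm = sample(c(TRUE, FALSE), 1),
                        t_arm = sample(c(TRUE, FALSE), 1), seed = 1000 + i)
    st1 <- fold_trna(tr$sequence, tr$anticodon_start)
    st2 <- fold_trna(tr$sequence, tr$anticodon_start)
    expect_identical(st1, st2)
    p <- trna_pairs(st1)
    expect_identical(anyDuplicated(as.vector(p)), 0L)
    expect_true(all(vapply(seq_len(nrow(p)), function(k)
      ok_pair(st1$sequence, p[k, 1], p[k, 2]), logical(1))))
    db <- trna_dot_bracket(st1)
    expect_identical(nchar(db), st1$length)
  }
})

test_that("acceptor-stem mismatches are recorded without flipping arm presence", {
  tr <- generate_trna("trnM", acceptor_mismatches = 2, seed = 77)
  st <- fold_trna(tr$sequence, tr$anticodon_start)
  expect_identical(st$acceptor_stem$mismatches, 2L)
  expect_identical(classify_trna(st), "cloverleaf")
  expect_identical(st$total_score,
                   2L * (sum(st$acceptor_stem$paired) + st$anticodon_arm$stem +
                           st$d_arm$stem + st$t_arm$stem) - 2L)
})

test_that("all 44 fixture tRNA annotations fall in the published 47-67 nt range", {
  lens <- unlist(lapply(c("Pt", "Es"), function(w) {
    r <- fixture_genome_table(w)$records
    r$end[r$class == "tRNA"] - r$start[r$class == "tRNA"] + 1
  }))
  expect_length(lens, 44)
  expect_true(all(lens >= 47 & lens <= 67))
})

test_that("the truncation summary aggregates counts, shared losses and sizes", {
  set.seed(42)
  fams <- names(mitoarch:::MT_ANTICODONS)
  shared_t_loss <- c("trnC", "trnF", "trnH")
  mk_genome <- function(seed_base, n_truncated = 16) {
    # choose which families are atypical; the three shared-loss families always are
    atypical <- union(shared_t_loss,
                      sample(setdiff(fams, shared_t_loss), n_truncated - 3))
    seqs <- lapply(seq_along(fams), function(i) {
      f <- fams[i]
      if (f %in% shared_t_loss) generate_trna(f, t_arm = FALSE, seed = seed_base + i)
      else if (f %in% atypical) generate_trna(f, d_arm = FALSE, seed = seed_base + i)
      else generate_trna(f, seed = seed_base + i)
    })
    stats::setNames(vapply(seqs, `[[`, "", "sequence"), fams)
  }
  panel <- list(g1 = fold_trna_set(mk_genome(0)), g2 = fold_trna_set(mk_genome(1000)))
  ts <- truncation_summary(panel)
  expect_identical(unname(ts$counts[, "atypical"]), c(16L, 16L))
  expect_identical(as.integer(rowSums(ts$counts[, 1:4])), c(22L, 22L))
  expect_true(all(shared_t_loss %in% ts$shared_loss$T_arm))
  expect_true(all(ts$size_range >= 40 & ts$size_range <= 100))
  # an all-cloverleaf panel has zero atypical structures
  clover <- fold_trna_set(stats::setNames(vapply(seq_along(fams), function(i)
    generate_trna(fams[i], seed = 5000 + i)$sequence, ""), fams))
  ts2 <- truncation_summary(list(g = clover))
  expect_identical(unname(ts2$counts[, "atypical"]), 0L)
})
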