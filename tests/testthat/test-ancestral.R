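test_that("the adjacency matrix covers the union of observed adjacencies", {
  fx <- fixture_orders()
  m <- build_adjacency_matrix(list(Pt = fx$pt, Es = fx$es, anc = fx$anc))
  expect_setequal(colnames(m),
                  unique(c(adjacency_set(fx$pt, "signed-circular"),
                           adjacency_set(fx$es, "signed-circular"),
                           adjacency_set(fx$anc, "signed-circular"))))
  expect_true(all(rowSums(m) == 37)) # n circular adjacencies per taxon
  # trnY-trnQ is a derived adjacency of the eriophyoids, absent in the ancestor
  yq <- intersect(adjacency_set(fx$pt, "signed-circular"),
                  adjacency_set(fx$es, "signed-circular"))
  yq <- yq[grepl("trnY", yq) & grepl("trnQ", yq)]
  expect_length(yq, 1)
  expect_true(all(m[c("Pt", "Es"), yq]))
  expect_false(m["anc", yq])
  # two identical orders share all their characters
  m2 <- build_adjacency_matrix(list(a = fx$anc, b = fx$anc))
  expect_true(all(m2[1, ] == m2[2, ]))
  expect_error(build_adjacency_matrix(list()), "no orders")
  expect_error(build_adjacency_matrix(list(x = fx$pt, x = fx$pt)), "duplicate")
})

test_that("parsimony handles constant and single-origin characters", {
  tree <- ape::read.tree(text = "((A,B),C);")
  m <- matrix(c(TRUE, TRUE, TRUE,
                TRUE, FALSE, FALSE), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("all", "onlyA")))
  fit <- fitch_ancestral_states(m, tree)
  expect_identical(unname(fit$changes["all"]), 0L)
  expect_true(all(vapply(fit$node_states, function(s) "all" %in% s$present, logical(1))))
  expect_identical(unname(fit$changes["onlyA"]), 1L)
  expect_true("onlyA" %in% fit$root$absent)
})

test_that("root ties are broken by the outgroup when one is flagged", {
  tree <- ape::read.tree(text = "(O,(A,B));")
  m <- matrix(c(TRUE, FALSE, FALSE), nrow = 3,
              dimnames = list(c("O", "A", "B"), "x"))
  fit_no <- fitch_ancestral_states(m, tree)
  expect_true("x" %in% fit_no$root$ambiguous)
  fit_og <- fitch_ancestral_states(m, tree, outgroup = "O")
  expect_true("x" %in% fit_og$root$present)
})

test_that("leaf/taxon mismatches are reported with offenders", {
  tree <- ape::read.tree(text = "((A,B),C);")
  m <- matrix(TRUE, nrow = 3, dimnames = list(c("A", "B", "D"), "x"))
  expect_error(fitch_ancestral_states(m, tree), "C")
  expect_error(fitch_ancestral_states(m, tree), "D")
})

test_that("parsimony change counts equal the exhaustive minimum on small trees", {
  set.seed(303)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    tree <- random_tree(n)
    states <- stats::setNames(sample(0:1, n, replace = TRUE), tree$tip.label)
    m <- matrix(as.logical(states), ncol = 1,
                dimnames = list(names(states), "x"))
    fit <- fitch_ancestral_states(m, tree)
    expect_identical(unname(fit$changes["x"]),
                     brute_force_changes(tree, states))
  }
})

test_that("a conflict-free circular adjacency set reassembles to its genome", {
  set.seed(404)
  for (i in 1:10) {
    o <- random_order(sample(5:12, 1))
    asm <- assemble_arrangement(adjacency_set(o, "signed-circular"))
    expect_true(asm$circular)
    expect_length(asm$fragments, 1)
    expect_length(asm$unplaced, 0)
    expect_true(orders_equal(gene_order(asm$fragments[[1]]$gene,
                                        asm$fragments[[1]]$orient), o))
  }
})

test_that("a gene with three incident adjacencies is reported as a conflict", {
  keys <- c(mitoarch:::signed_key("cox1", "+", "cox2", "+"),
            mitoarch:::signed_key("cox3", "+", "cox2", "+"),
            mitoarch:::signed_key("cox2", "+", "cob", "+"),
            mitoarch:::signed_key("cob", "+", "nad1", "+"))
  asm <- assemble_arrangement(keys)
  expect_true("cox2" %in% asm$conflicts)
  expect_true("cox2" %in% asm$unplaced)
  # fragments split at the conflicted gene: cob-nad1 survives as a path
  expect_true(any(vapply(asm$fragments, function(f)
    all(c("cob", "nad1") %in% f$gene), logical(1))))
  expect_false(any(vapply(asm$fragments, function(f) "cox2" %in% f$gene, logical(1))))
})

test_that("the Acariformes root inferred on the packaged topology leaves trnQ and trnY unplaced", {
  orders <- c(fixture_screen_orders(),
              list(Phyllocoptes_taishanensis = gene_order_from_table(fixture_genome_table("Pt")),
                   Epitrimerus_sabinae = gene_order_from_table(fixture_genome_table("Es"))))
  m <- build_adjacency_matrix(orders)
  tree <- fixture_tree()
  fit <- fitch_ancestral_states(m, tree, outgroup = "Limulus_polyphemus")
  acari <- c("Phyllocoptes_taishanensis", "Epitrimerus_sabinae",
             "Tetranychus_urticae", "Demodex_sp", "Leptotrombidium_pallidum",
             "Unionicola_parkeri", "Dermatophagoides_sp", "Steganacarus_magnus")
  node <- ape::getMRCA(tree, acari)
  st <- fit$node_states[[as.character(node)]]
  asm <- assemble_arrangement(st$present, genes = mitoarch:::MT_GENES)
  expect_true(all(c("trnQ", "trnY") %in% asm$unplaced))
  # the conserved protein-coding backbone is recovered as one fragment
  expect_true(any(vapply(asm$fragments, function(f)
    all(c("cox1", "cox2", "atp6", "cox3", "nad3") %in% f$gene), logical(1))))
})
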