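test_that("adjacency sets follow their conventions on toy circles", {
  toy <- gene_order(c("cox1", "cox2", "cox3"))
  sc <- adjacency_set(toy, "signed-circular")
  expect_length(sc, 3)
  ul <- adjacency_set(toy, "unsigned-linear-cox1")
  expect_length(ul, 2)
  expect_setequal(ul, c("cox1|cox2", "cox2|cox3"))
  # reverse complement leaves both conventions invariant
  rc <- revcomp_order(toy)
  expect_setequal(adjacency_set(rc, "signed-circular"), sc)
  expect_setequal(adjacency_set(rc, "unsigned-linear-cox1"), ul)
  expect_error(adjacency_set(gene_order(c("cox2", "cox3")), "unsigned-linear-cox1"),
               "cox1")
})

test_that("the eriophyoid orders have 36 linear adjacencies including the novel ones", {
  fx <- fixture_orders()
  a <- adjacency_set(fx$pt)
  expect_length(a, 36)
  expect_true(all(c("trnI|trnS1", "trnQ|trnY") %in% a))
})

test_that("breakpoint distances reproduce the published comparison", {
  fx <- fixture_orders()
  expect_identical(breakpoint_distance(fx$pt, fx$anc), 13L)
  expect_identical(breakpoint_distance(fx$es, fx$anc), 16L)
  expect_identical(breakpoint_distance(fx$anc, fx$anc), 0L)
})

test_that("distance is zero on self, invariant to rotation and reflection", {
  set.seed(101)
  for (i in 1:20) {
    o <- random_order(sample(4:12, 1))
    expect_identical(breakpoint_distance(o, o), 0L)
    o2 <- random_order(nrow(o))
    o2 <- gene_order(sample(o$gene), sample(c("+", "-"), nrow(o), TRUE))
    d <- breakpoint_distance(o2, o)
    expect_identical(breakpoint_distance(rotate_order(o2, 3), o), d)
    expect_identical(breakpoint_distance(revcomp_order(o2), o), d)
    expect_identical(breakpoint_distance(o2, revcomp_order(rotate_order(o, 2))), d)
  }
})

test_that("moving one gene of a six-gene circle creates three breakpoints", {
  ref <- gene_order(c("cox1", "cox2", "cox3", "cob", "nad1", "nad2"))
  tgt <- gene_order(c("cox1", "cox2", "cob", "nad1", "cox3", "nad2"))
  # hand enumeration: {cox2,cob}, {nad1,cox3}, {cox3,nad2} are new
  expect_identical(breakpoint_distance(tgt, ref), 3L)
  expect_setequal(derived_adjacencies(tgt, ref),
                  c("cob|cox2", "cox3|nad1", "cox3|nad2"))
})

test_that("derived adjacencies are the set difference behind the distance", {
  fx <- fixture_orders()
  expect_length(derived_adjacencies(fx$anc, fx$anc), 0)
  d <- derived_adjacencies(fx$pt, fx$anc)
  expect_length(d, 13)
  expect_true(all(c("trnQ|trnY", "nad6|trnT") %in% d))
  expect_false("nad2|trnW" %in% d) # ancestor has nad2-trnW; unsigned pairs fold
})

test_that("gene-set mismatches abort with the symmetric difference named", {
  a <- gene_order(c("cox1", "cox2", "cox3"))
  b <- gene_order(c("cox1", "cox2", "cob"))
  expect_error(breakpoint_distance(a, b), "cox3")
  expect_error(breakpoint_distance(a, b), "cob")
})

test_that("distance agrees with a brute-force adjacency enumerator", {
  set.seed(202)
  for (i in 1:100) {
    k <- sample(4:10, 1)
    a <- random_order(k)
    b <- gene_order(sample(a$gene), sample(c("+", "-"), k, TRUE))
    expect_identical(breakpoint_distance(b, a),
                     as.integer(bf_breakpoints(b, a)))
  }
})

test_that("a target identical to the reference yields no clusters", {
  anc <- fixture_orders()$anc
  expect_length(shared_derived_clusters(list(anc), anc), 0)
})

test_that("the shared derived runs of the two eriophyoid mites include the published clusters", {
  fx <- fixture_orders()
  cl <- shared_derived_clusters(list(fx$pt, fx$es), fx$anc)
  runs <- lapply(cl, `[[`, "genes")
  has_run <- function(run) any(vapply(runs, function(g)
    order_contains_run(gene_order(g$gene, g$orient), run), logical(1)))
  expect_true(has_run(c("trnS1", "trnI", "trnE")))
  expect_true(has_run(c("nad6", "trnT", "cob")))
  expect_true(has_run(c("trnY", "trnQ", "rrnS", "trnV", "rrnL")))
  expect_true(has_run(c("trnW", "nad2", "trnM", "-trnC")))
})

test_that("run-level screening refutes clusters found in other mites", {
  fx <- fixture_orders()
  screen <- fixture_screen_orders()
  cl <- shared_derived_clusters(list(fx$pt, fx$es), fx$anc, screen = screen)
  by_genes <- function(gs) Filter(function(c0) gs %in% c0$genes$gene &&
                                    length(gs) > 0, cl)
  # the nad4L-trnP junction is shared-derived but occurs in screened mites
  nad4l <- Filter(function(c0) "nad4L" %in% c0$genes$gene, cl)
  expect_length(nad4l, 1)
  expect_false(nad4l[[1]]$synapomorphic)
  expect_true(length(nad4l[[1]]$present_in_screen) > 0)
  # surviving clusters cover the four published runs
  surv <- Filter(function(c0) c0$synapomorphic, cl)
  runs <- lapply(surv, `[[`, "genes")
  has_run <- function(run) any(vapply(runs, function(g)
    order_contains_run(gene_order(g$gene, g$orient), run), logical(1)))
  for (run in list(c("trnS1", "trnI", "trnE"), c("nad6", "trnT", "cob"),
                   c("trnY", "trnQ", "rrnS", "trnV", "rrnL"),
                   c("trnW", "nad2", "trnM", "-trnC"))) {
    expect_true(has_run(run))
  }
})

test_that("arrangement exchange files round-trip", {
  fx <- fixture_orders()
  tmp <- tempfile(fileext = ".txt")
  write_arrangements(list(fx$pt, fx$anc), tmp)
  back <- read_arrangements(tmp)
  expect_setequal(names(back),
                  c("Phyllocoptes_taishanensis", "Hypothetical_arthropod_ancestor"))
  expect_true(orders_equal(back$Phyllocoptes_taishanensis, fx$pt))
  expect_true(orders_equal(back$Hypothetical_arthropod_ancestor, fx$anc))
  expect_identical(back$Hypothetical_arthropod_ancestor$gene, fx$anc$gene)
})

test_that("circular order equality is rotation and reflection invariant", {
  o <- random_order(8)
  expect_true(orders_equal(o, rotate_order(o, 5)))
  expect_true(orders_equal(o, revcomp_order(rotate_order(o, 2))))
  o2 <- o
  o2$orient[3] <- if (o2$orient[3] == "+") "-" else "+"
  expect_false(orders_equal(o, o2))
})
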