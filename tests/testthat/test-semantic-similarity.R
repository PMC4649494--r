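chain_edges <- data.frame(parent = c("R", "X"), child = c("X", "A"))
diamond_edges <- data.frame(parent = c("R", "R", "X", "Y"),
                            child = c("X", "Y", "A", "A"))

test_that("ancestor closure builds the expected DAGs", {
  root <- build_dag("R", chain_edges, terms = "R")
  expect_identical(root$nodes, "R")
  expect_equal(nrow(root$edges), 0)

  chain <- build_dag("A", chain_edges)
  expect_identical(chain$nodes, c("A", "R", "X"))
  expect_equal(nrow(chain$edges), 2)

  diamond <- build_dag("A", diamond_edges)
  expect_identical(diamond$nodes, c("A", "R", "X", "Y"))
  expect_equal(nrow(diamond$edges), 4)

  expect_error(build_dag("Z", chain_edges), "not in ontology")
  cyc <- data.frame(parent = c("A", "B"), child = c("B", "A"))
  expect_error(build_dag("A", cyc), "cycle")
})

test_that("multiple tree positions merge into one DAG", {
  edges <- data.frame(parent = c("R1", "R2"), child = c("A1", "A2"))
  dag <- build_dag("dA", edges, terms = c("A1", "A2"))
  expect_identical(dag$nodes, c("A1", "A2", "R1", "R2"))
})

test_that("term contribution is the corpus information content", {
  map <- data.frame(disease_id = c("d1", "d2", "d3", "d4"),
                    term_id = c("A", "B", "C", "D"))
  edges <- data.frame(parent = rep("R", 4), child = c("A", "B", "C", "D"))
  corpus <- dag_corpus(edges, map)
  expect_equal(term_contribution("R", corpus), 0)          # in all 4 DAGs
  expect_equal(term_contribution("A", corpus), -log(1 / 4))
  expect_equal(term_contribution("A", corpus, base = 2), -log2(1 / 4))
  expect_error(term_contribution("Z", corpus), "absent")
  # rarer terms contribute strictly more
  expect_gt(term_contribution("A", corpus), term_contribution("R", corpus))
})

test_that("semantic value sums contributions over the closure", {
  # single-disease corpus: every term occurs in the only DAG -> DV = 0
  solo <- dag_corpus(chain_edges, data.frame(disease_id = "d", term_id = "A"))
  expect_equal(semantic_value(solo$dags[["d"]], solo), 0)

  # D(A) = {R, A}, R in both of 2 DAGs, A in 1 of 2 -> DV(A) = log 2
  edges <- data.frame(parent = c("R", "R"), child = c("A", "B"))
  corpus <- dag_corpus(edges, data.frame(disease_id = c("dA", "dB"),
                                         term_id = c("A", "B")))
  expect_equal(semantic_value(corpus$dags[["dA"]], corpus), log(2))

  # a sub-DAG never has larger semantic value (nonnegative summands)
  corpus3 <- dag_corpus(chain_edges,
                        data.frame(disease_id = c("dX", "dA"),
                                   term_id = c("X", "A")))
  expect_gte(semantic_value(corpus3$dags[["dA"]], corpus3),
             semantic_value(corpus3$dags[["dX"]], corpus3))
})

test_that("semantic similarity identities hold", {
  edges <- data.frame(parent = c("R", "R", "S"), child = c("A", "B", "C"))
  corpus <- dag_corpus(edges,
                       data.frame(disease_id = c("dA", "dB", "dC"),
                                  term_id = c("A", "B", "C")))
  expect_equal(semantic_similarity("dA", "dA", corpus), 1)
  expect_equal(semantic_similarity("dA", "dC", corpus), 0)  # disjoint DAGs
  expect_equal(semantic_similarity("dA", "dB", corpus),
               semantic_similarity("dB", "dA", corpus))
  # shared parent R (in 2 of 3 DAGs): hand enumeration
  # contrib(R) = -log(2/3); contrib(A) = contrib(B) = -log(1/3)
  # DV(dA) = DV(dB) = -log(2/3) - log(1/3); shared = {R}
  hand <- 2 * (-log(2 / 3)) / (2 * (-log(2 / 3) - log(1 / 3)))
  s <- semantic_similarity("dA", "dB", corpus)
  expect_equal(s, hand)
  expect_gt(s, 0)
  expect_lt(s, 1)
  expect_error(semantic_similarity("dA", "nope", corpus), "absent")
})

test_that("degenerate zero semantic values warn and keep the unit diagonal", {
  solo <- dag_corpus(chain_edges, data.frame(disease_id = "d", term_id = "A"))
  expect_warning(v <- semantic_similarity("d", "d", solo), "degenerate")
  expect_equal(v, 1)
  expect_warning(m <- semantic_similarity_matrix(solo), "degenerate")
  expect_identical(unname(unclass(m)[1, 1]), 1)
})

test_that("similarity matrix equals pairwise calls and is exactly symmetric", {
  spec <- fixture_spec(nd = 12, n_blocks = 3, seed = 11)
  onto <- synthetic_dag_corpus(spec, sprintf("D%02d", 1:12))
  corpus <- dag_corpus(onto$edges, onto$map)
  m <- semantic_similarity_matrix(corpus)
  expect_identical(unclass(m), t(unclass(m)))
  expect_true(all(m >= 0 & m <= 1))
  for (a in rownames(m)) for (b in colnames(m)) {
    expect_equal(m[a, b], semantic_similarity(a, b, corpus))
  }
  expect_equal(nrow(semantic_similarity_matrix(corpus, character(0))), 0)
})

test_that("similarity agrees with a brute-force closure oracle on random corpora", {
  for (seed in 1:5) {
    spec <- fixture_spec(nd = 10, n_blocks = 2, dag_depth = 4, seed = seed)
    ids <- sprintf("D%02d", 1:10)
    onto <- synthetic_dag_corpus(spec, ids)
    corpus <- dag_corpus(onto$edges, onto$map)
    terms_of <- function(d) onto$map$term_id[onto$map$disease_id == d]
    ds <- names(corpus$dags)
    all_terms <- lapply(ds, terms_of)
    pick <- utils::combn(seq_along(ds), 2)[, 1:8]
    for (c_ in seq_len(ncol(pick))) {
      i <- pick[1, c_]; j <- pick[2, c_]
      expect_equal(semantic_similarity(ds[i], ds[j], corpus),
                   ss_oracle(all_terms[[i]], all_terms[[j]], all_terms,
                             onto$edges),
                   tolerance = 1e-12)
    }
  }
})

test_that("making a shared ancestor rarer never decreases similarity", {
  # same DAG pair evaluated in two corpora differing only in how many other
  # DAGs contain the shared parent P
  for (extra in 0:3) {
    build <- function(n_with_p) {
      others <- sprintf("o%d", 1:4)
      par <- c("P", "P", rep("Q", 4))
      chl <- c("A", "B", others)
      if (n_with_p > 0) {
        par <- c(par, rep("P", n_with_p))
        chl <- c(chl, others[seq_len(n_with_p)])
      }
      edges <- unique(data.frame(parent = par, child = chl))
      map <- data.frame(disease_id = c("dA", "dB", sprintf("do%d", 1:4)),
                        term_id = c("A", "B", others))
      semantic_similarity("dA", "dB", dag_corpus(edges, map))
    }
    expect_gte(build(extra), build(extra + 1))
  }
})
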