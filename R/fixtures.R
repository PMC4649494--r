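#' Specification for the synthetic data generators
#'
#' Bundles the knobs shared by all generators. The defaults define the
#' package's standard benchmark condition: a 60 x 40 bipartite network at
#' density 0.05 with 4 paired lncRNA/disease modules, a depth-4 ontology,
#' and 22 tissues (mirroring the tissue panel size of genome-browser
#' lincRNA expression profiles), sized so the full cross-validation suite
#' runs in minutes on one CPU.
#'
#' @param nl,nd numbers of lncRNAs and diseases.
#' @param density expected fraction of 1s in the adjacency matrix, in (0,1).
#' @param dag_depth,dag_branching shape of the layered random ontology.
#' @param n_tissues number of expression columns.
#' @param n_blocks number of latent modules on each side.
#' @param signal_strength in [0.5, 1]: 0.5 means associations ignore the
#'   module structure, 1 means all associations respect it.
#' @param annotated_fraction fraction of diseases receiving ontology
#'   annotation (the \code{IS} set).
#' @param profiled_fraction fraction of lncRNAs with expression profiles.
#' @param noise_sd log-scale noise of the expression generator.
#' @param seed integer master seed; each generator derives its own
#'   sub-stream from it (see Details).
#'
#' @details Every generator seeds its own stream as
#'   \code{(seed * 101 + offset) mod (2^31 - 1)} with a fixed per-generator
#'   offset, so adding a generator or reordering calls never perturbs the
#'   fixtures another generator produces from the same master seed.
#' @return a \code{fixture_spec} list.
#' @export
fixture_spec <- function(nl = 60, nd = 40, density = 0.05,
                         dag_depth = 4, dag_branching = 2,
                         n_tissues = 22, n_blocks = 4,
                         signal_strength = 0.8,
                         annotated_fraction = 0.8,
                         profiled_fraction = 0.8,
                         noise_sd = 0.5, seed = 1) {
  stopifnot(nl >= 1, nd >= 1, density > 0, density < 1,
            dag_depth >= 2, dag_branching >= 1, n_tissues >= 2,
            n_blocks >= 1, signal_strength >= 0.5, signal_strength <= 1,
            annotated_fraction > 0, annotated_fraction <= 1,
            profiled_fraction > 0, profiled_fraction <= 1, noise_sd >= 0)
  structure(as.list(environment()), class = "fixture_spec")
}

sub_seed <- function(seed, stream) {
  offsets <- c(network = 11, dag = 29, expression = 47, planted = 73,
               functional = 89, reference = 97)
  as.integer((as.numeric(seed) * 101 + offsets[[stream]]) %% 2147483647)
}

fixture_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

block_labels <- function(n, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n))
}

#' Random Bernoulli bipartite association network
#'
#' Each cell of the adjacency matrix is an independent Bernoulli draw at
#' the spec's density; an empty draw is resampled so at least one
#' association exists.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return an \code{\link{association_network}}.
#' @export
random_network <- function(spec) {
  set.seed(sub_seed(spec$seed, "network"))
  repeat {
    A <- matrix(stats::rbinom(spec$nl * spec$nd, 1, spec$density),
                spec$nl, spec$nd)
    if (sum(A) > 0) break
  }
  association_network(fixture_ids("L", spec$nl), fixture_ids("D", spec$nd), A)
}

#' Layered random disease ontology with annotation map
#'
#' Emulates the ontology input of the semantic-similarity module: a global
#' acyclic parent-to-child edge list plus a mapping from disease
#' identifiers to ontology terms. The DAG is layered (a root, one subtree
#' head per module, \code{dag_depth - 1} internal levels below each head),
#' and edges only ever point from one layer to a deeper one, so the graph
#' is acyclic by construction. A random subset of the diseases (the
#' \code{annotated_fraction}) receives a leaf term attached under its
#' module's subtree — diseases sharing a module share ancestors, making
#' them semantically similar — with occasional cross-module parents for
#' realistic overlap. Unannotated diseases are absent from the map,
#' emulating diseases lacking ontology descriptors.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param disease_ids disease identifiers to annotate; defaults to the ids
#'   \code{random_network(spec)} would generate.
#' @param disease_blocks optional integer module label per disease
#'   (defaults to contiguous equal blocks).
#' @return list with \code{edges} (parent, child), \code{map}
#'   (disease_id, term_id) and \code{annotated} (character vector).
#' @export
synthetic_dag_corpus <- function(spec, disease_ids = fixture_ids("D", spec$nd),
                                 disease_blocks = NULL) {
  set.seed(sub_seed(spec$seed, "dag"))
  nd <- length(disease_ids)
  if (is.null(disease_blocks))
    disease_blocks <- block_labels(nd, spec$n_blocks)
  n_ann <- max(1L, round(spec$annotated_fraction * nd))
  annotated <- sort(sample(disease_ids, n_ann), method = "radix")

  root <- "T:root"
  parents <- character(0)
  children <- character(0)
  level_nodes <- vector("list", spec$n_blocks)
  for (b in seq_len(spec$n_blocks)) {
    head <- sprintf("T:b%d", b)
    parents <- c(parents, root)
    children <- c(children, head)
    levels <- list(head)
    for (l in seq_len(spec$dag_depth - 1)) {
      nodes <- sprintf("T:b%d.%d.%d", b, l, seq_len(spec$dag_branching))
      prev <- levels[[l]]
      for (nd_ in nodes) {
        parents <- c(parents, sample(prev, 1))
        children <- c(children, nd_)
      }
      levels[[l + 1]] <- nodes
    }
    level_nodes[[b]] <- levels
  }

  map <- data.frame(disease_id = character(0), term_id = character(0))
  for (d in annotated) {
    b <- disease_blocks[match(d, disease_ids)]
    term <- sprintf("t:%s", d)
    deepest <- level_nodes[[b]][[spec$dag_depth]]
    parents <- c(parents, sample(deepest, 1))
    children <- c(children, term)
    if (stats::runif(1) < 0.2) {  # occasional cross-module ancestry
      ob <- sample(seq_len(spec$n_blocks), 1)
      pool <- unlist(level_nodes[[ob]])
      parents <- c(parents, sample(pool, 1))
      children <- c(children, term)
    }
    map <- rbind(map, data.frame(disease_id = d, term_id = term))
  }
  edges <- unique(data.frame(parent = parents, child = children))
  list(edges = edges, map = map, annotated = annotated)
}

#' Block-correlated synthetic expression profiles
#'
#' lncRNAs are assigned to latent modules; profiles within a module share a
#' latent tissue pattern perturbed by seeded log-normal noise, so
#' within-module Spearman correlation exceeds between-module correlation in
#' expectation (and equals 1 exactly at zero noise). A random subset of
#' lncRNAs (the \code{profiled_fraction}) receives profiles, emulating the
#' lincRNA subset with available expression data.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param lncrna_ids lncRNA identifiers; defaults to the generated ids.
#' @param lncrna_blocks optional module label per lncRNA.
#' @return an \code{\link{expression_profile_set}} over the profiled subset.
#' @export
synthetic_expression <- function(spec, lncrna_ids = fixture_ids("L", spec$nl),
                                 lncrna_blocks = NULL) {
  set.seed(sub_seed(spec$seed, "expression"))
  nl <- length(lncrna_ids)
  if (is.null(lncrna_blocks)) lncrna_blocks <- block_labels(nl, spec$n_blocks)
  n_prof <- max(2L, round(spec$profiled_fraction * nl))
  profiled <- sort(sample(lncrna_ids, n_prof), method = "radix")
  patterns <- matrix(stats::rnorm(spec$n_blocks * spec$n_tissues),
                     spec$n_blocks, spec$n_tissues)
  values <- t(vapply(profiled, function(id) {
    b <- lncrna_blocks[match(id, lncrna_ids)]
    exp(patterns[b, ] + stats::rnorm(spec$n_tissues, 0, spec$noise_sd))
  }, numeric(spec$n_tissues)))
  expression_profile_set(profiled, sprintf("tissue%02d", seq_len(spec$n_tissues)),
                         values)
}

#' Noisy synthetic lncRNA functional similarity matrix
#'
#' Emulates a precomputed functional-similarity input: high baseline
#' similarity within a module, low between, perturbed by seeded uniform
#' noise, symmetrized and clamped to [0, 1], over a covered subset of the
#' lncRNAs.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param lncrna_ids lncRNA identifiers.
#' @param lncrna_blocks optional module label per lncRNA.
#' @param covered_fraction fraction of lncRNAs the file covers.
#' @return a labeled square base matrix (as a loader would read it).
#' @export
synthetic_functional_similarity <- function(spec,
                                            lncrna_ids = fixture_ids("L", spec$nl),
                                            lncrna_blocks = NULL,
                                            covered_fraction = 0.7) {
  set.seed(sub_seed(spec$seed, "functional"))
  nl <- length(lncrna_ids)
  if (is.null(lncrna_blocks)) lncrna_blocks <- block_labels(nl, spec$n_blocks)
  n_cov <- max(2L, round(covered_fraction * nl))
  covered <- sort(sample(lncrna_ids, n_cov), method = "radix")
  b <- lncrna_blocks[match(covered, lncrna_ids)]
  base <- ifelse(outer(b, b, "=="), 0.8, 0.2)
  noise <- matrix(stats::runif(n_cov^2, -0.1, 0.1), n_cov, n_cov)
  m <- base + (noise + t(noise)) / 2
  m <- pmin(pmax(m, 0), 1)
  diag(m) <- 1
  dimnames(m) <- list(covered, covered)
  m
}

#' Bipartite network with planted module signal
#'
#' lncRNA and disease modules are paired one-to-one; association
#' probabilities inside paired modules are raised and outside lowered while
#' keeping the overall expected density at the spec's value. Writing
#' \code{s = 2 * signal_strength - 1} and \code{f} for the fraction of
#' cells inside paired modules, the outside probability is
#' \code{density * (1 - s)} and the inside probability is solved from the
#' density constraint; \code{signal_strength = 0.5} therefore reduces to a
#' uniform Bernoulli network with no planted structure, and
#' \code{signal_strength = 1} concentrates all associations inside the
#' paired modules (near-block-diagonal adjacency). Each paired module is
#' guaranteed at least one association.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return list with \code{net} (an \code{\link{association_network}}),
#'   \code{lncrna_blocks} and \code{disease_blocks}.
#' @export
planted_signal_network <- function(spec) {
  set.seed(sub_seed(spec$seed, "planted"))
  lb <- block_labels(spec$nl, spec$n_blocks)
  db <- block_labels(spec$nd, spec$n_blocks)
  inside <- outer(lb, db, "==")
  f <- mean(inside)
  s <- 2 * spec$signal_strength - 1
  p_out <- spec$density * (1 - s)
  p_in <- (spec$density - (1 - f) * p_out) / f
  if (p_in > 1) {
    warning("inside-module probability capped at 1")
    p_in <- 1
  }
  P <- ifelse(inside, p_in, p_out)
  A <- matrix(stats::rbinom(spec$nl * spec$nd, 1, as.vector(P)),
              spec$nl, spec$nd)
  for (b in seq_len(spec$n_blocks)) {
    cells <- which(outer(lb == b, db == b, "&"), arr.ind = TRUE)
    if (nrow(cells) > 0 && sum(A[cells]) == 0) {
      pick <- cells[sample(nrow(cells), 1), , drop = FALSE]
      A[pick] <- 1
    }
  }
  net <- association_network(fixture_ids("L", spec$nl),
                             fixture_ids("D", spec$nd), A)
  list(net = net, lncrna_blocks = lb, disease_blocks = db)
}

#' Full planted-signal input bundle
#'
#' Generates, from one spec, every input the prediction pipeline consumes,
#' with the similarity structure aligned to the planted association
#' modules: the network, the semantic similarity matrix over the annotated
#' disease subset (via the ontology generator), the expression similarity
#' and the functional similarity.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return list with \code{net}, \code{ss}, \code{es}, \code{fs},
#'   \code{lncrna_blocks}, \code{disease_blocks}.
#' @export
planted_fixture <- function(spec) {
  pl <- planted_signal_network(spec)
  onto <- synthetic_dag_corpus(spec, pl$net$disease_ids, pl$disease_blocks)
  corpus <- dag_corpus(onto$edges, onto$map)
  ss <- semantic_similarity_matrix(corpus)
  expr <- synthetic_expression(spec, pl$net$lncrna_ids, pl$lncrna_blocks)
  es <- expression_similarity(expr, pl$net$lncrna_ids)
  fsm <- synthetic_functional_similarity(spec, pl$net$lncrna_ids,
                                         pl$lncrna_blocks)
  fs <- functional_similarity_from_matrix(fsm, pl$net$lncrna_ids)
  list(net = pl$net, ss = ss, es = es, fs = fs,
       lncrna_blocks = pl$lncrna_blocks, disease_blocks = pl$disease_blocks)
}

#' Synthetic stand-in for the curated gold-standard association table
#'
#' Generates a random network with the same dimensions as the curated
#' lncRNA-disease gold standard (by default 293 distinct pairs over 118
#' lncRNAs and 167 diseases, every entity covered). The topology is
#' synthetic; only the counts are meaningful.
#'
#' @param nl,nd,n_assoc dimensions and number of distinct associations.
#' @param seed integer seed.
#' @return an \code{\link{association_network}}.
#' @export
synthetic_reference_network <- function(nl = 118, nd = 167, n_assoc = 293,
                                        seed = 1) {
  if (n_assoc < max(nl, nd) || n_assoc > nl * nd)
    stop("n_assoc cannot cover every lncRNA and disease")
  set.seed(sub_seed(seed, "reference"))
  pairs <- cbind(sample.int(nl, nd, replace = TRUE), seq_len(nd))
  uncovered <- setdiff(seq_len(nl), pairs[, 1])
  if (length(uncovered) > 0)
    pairs <- rbind(pairs, cbind(uncovered,
                                sample.int(nd, length(uncovered),
                                           replace = TRUE)))
  pairs <- unique(pairs)
  cells <- seq_len(nl * nd)
  used <- (pairs[, 2] - 1) * nl + pairs[, 1]
  extra <- sample(setdiff(cells, used), n_assoc - nrow(pairs))
  A <- matrix(0, nl, nd)
  A[c(used, extra)] <- 1
  stopifnot(sum(A) == n_assoc, all(rowSums(A) > 0), all(colSums(A) > 0))
  association_network(fixture_ids("L", nl), fixture_ids("D", nd), A)
}

#' Write all synthetic pipeline inputs to disk
#'
#' Emits, in the exact formats the loaders consume: the association pair
#' list, the ontology edge list and disease-term map, the expression
#' matrix, and the functional similarity matrix.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_files <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pl <- planted_signal_network(spec)
  onto <- synthetic_dag_corpus(spec, pl$net$disease_ids, pl$disease_blocks)
  expr <- synthetic_expression(spec, pl$net$lncrna_ids, pl$lncrna_blocks)
  fsm <- synthetic_functional_similarity(spec, pl$net$lncrna_ids,
                                         pl$lncrna_blocks)
  paths <- c(associations = file.path(dir, "associations.tsv"),
             ontology_edges = file.path(dir, "ontology_edges.tsv"),
             ontology_map = file.path(dir, "ontology_map.tsv"),
             expression = file.path(dir, "expression.tsv"),
             functional = file.path(dir, "functional_similarity.tsv"))
  write_associations(pl$net, paths[["associations"]])
  utils::write.table(onto$edges, paths[["ontology_edges"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(onto$map, paths[["ontology_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  edf <- data.frame(lincrna_id = expr$lincrna_ids, expr$values,
                    check.names = FALSE)
  utils::write.table(edf, paths[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix_tsv(fsm, paths[["functional"]])
  invisible(paths)
}
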