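#' Build the ancestor-closed DAG of a disease term
#'
#' Each disease with an ontology annotation is represented by
#' \code{DAG(A) = (D(A), E(A))}: \code{D(A)} is the disease term itself plus
#' all of its ancestors in the ontology, and \code{E(A)} is the set of
#' parent-to-child edges of the global ontology with both endpoints in
#' \code{D(A)}. Multiple tree positions (several terms mapping to one
#' disease) merge into a single DAG by taking the union of the closures.
#'
#' @param disease identifier of the disease the DAG describes.
#' @param parent_edges data frame (or 2-column matrix) of global ontology
#'   edges, column 1 the parent term, column 2 the child term.
#' @param terms ontology term id(s) annotating the disease; defaults to
#'   \code{disease} itself.
#' @return object of class \code{disease_dag}: list with \code{disease},
#'   \code{nodes} (character) and \code{edges} (2-column data frame).
#' @export
build_dag <- function(disease, parent_edges, terms = disease) {
  g <- ontology_graph(parent_edges)
  missing <- setdiff(terms, igraph::V(g)$name)
  if (length(missing) > 0)
    stop(sprintf("term(s) not in ontology: %s",
                 paste(missing, collapse = ", ")))
  nodes <- unique(unlist(lapply(terms, function(t)
    names(igraph::subcomponent(g, t, mode = "in")))))
  ed <- as.data.frame(parent_edges[, 1:2])
  names(ed) <- c("parent", "child")
  ed$parent <- trimws(as.character(ed$parent))
  ed$child <- trimws(as.character(ed$child))
  keep <- ed$parent %in% nodes & ed$child %in% nodes
  structure(
    list(disease = disease, nodes = sort(nodes, method = "radix"),
         edges = ed[keep, , drop = FALSE]),
    class = "disease_dag"
  )
}

# validated igraph object for a parent->child edge list
ontology_graph <- function(parent_edges) {
  ed <- as.data.frame(parent_edges[, 1:2])
  ed[] <- lapply(ed, function(x) trimws(as.character(x)))
  g <- igraph::graph_from_data_frame(ed, directed = TRUE)
  if (!igraph::is_dag(g))
    stop("structural error: ontology edge list contains a cycle")
  g
}

#' Build a corpus of disease DAGs with term occurrence counts
#'
#' The corpus holds one ancestor-closed DAG per annotated disease together
#' with, for every ontology term, the number of DAGs whose node set contains
#' it. That count drives the specificity weighting: terms appearing in fewer
#' disease DAGs are more specific and contribute more semantic value.
#'
#' @param parent_edges global ontology edge list (parent, child).
#' @param disease_map data frame mapping \code{disease_id} to
#'   \code{term_id}; a disease may map to several terms (several tree
#'   positions). Diseases absent from the map are simply not in the corpus.
#' @return object of class \code{dag_corpus}: list with \code{dags} (named
#'   list of \code{disease_dag}), \code{term_dag_count} (named integer) and
#'   \code{n_diseases}.
#' @export
dag_corpus <- function(parent_edges, disease_map) {
  disease_map <- as.data.frame(disease_map)
  names(disease_map)[1:2] <- c("disease_id", "term_id")
  g <- ontology_graph(parent_edges)  # validates acyclicity once
  diseases <- unique(as.character(disease_map$disease_id))
  dags <- lapply(diseases, function(d) {
    terms <- disease_map$term_id[disease_map$disease_id == d]
    build_dag(d, parent_edges, terms = as.character(terms))
  })
  names(dags) <- diseases
  counts <- table(unlist(lapply(dags, function(x) x$nodes)))
  structure(
    list(dags = dags,
         term_dag_count = stats::setNames(as.integer(counts), names(counts)),
         n_diseases = length(dags)),
    class = "dag_corpus"
  )
}

#' @export
print.dag_corpus <- function(x, ...) {
  cat(sprintf("dag_corpus: %d disease DAGs over %d ontology terms\n",
              x$n_diseases, length(x$term_dag_count)))
  invisible(x)
}

#' Specificity-weighted contribution of an ontology term
#'
#' A term occurring in fewer disease DAGs describes a more specific disease
#' and should contribute more semantic value. The contribution is the
#' information content of the term within the corpus,
#' \code{-log(term_dag_count(t) / n_diseases)}: strictly decreasing in the
#' occurrence count and zero for a term present in every DAG.
#'
#' @param term ontology term id.
#' @param corpus a \code{\link{dag_corpus}}.
#' @param base logarithm base (default \code{exp(1)}; cancels in the
#'   similarity ratio).
#' @return nonnegative contribution value.
#' @export
term_contribution <- function(term, corpus, base = exp(1)) {
  cnt <- corpus$term_dag_count[term]
  if (anyNA(cnt))
    stop(sprintf("term(s) absent from corpus: %s",
                 paste(term[is.na(cnt)], collapse = ", ")))
  -log(unname(cnt) / corpus$n_diseases) / log(base)
}

#' Semantic value of a disease DAG
#'
#' Sum of the contributions of the disease term itself and all its
#' ancestors: \code{DV(A) = sum over t in D(A) of contribution(t)}.
#'
#' @param dag a \code{\link{build_dag}} result.
#' @param corpus a \code{\link{dag_corpus}} providing occurrence counts.
#' @param base logarithm base.
#' @return nonnegative semantic value.
#' @export
semantic_value <- function(dag, corpus, base = exp(1)) {
  sum(term_contribution(dag$nodes, corpus, base = base))
}

#' Semantic similarity between two diseases
#'
#' Shared ancestry measured on the two DAGs:
#' \deqn{SS(A,B) = \frac{\sum_{t \in D(A) \cap D(B)} (D_A(t) + D_B(t))}
#'                     {DV(A) + DV(B)}}
#' where the contribution of a shared term is counted from both sides.
#' Symmetric, in [0, 1], and 1 on the diagonal. In the degenerate case
#' \code{DV(A) + DV(B) = 0} (every term occurs in all DAGs of the corpus)
#' the similarity is defined as 1 for identical diseases and 0 otherwise,
#' with a warning.
#'
#' @param a,b disease identifiers present in the corpus.
#' @param corpus a \code{\link{dag_corpus}}.
#' @param base logarithm base.
#' @return similarity in [0, 1].
#' @export
semantic_similarity <- function(a, b, corpus, base = exp(1)) {
  da <- corpus$dags[[a]]
  db <- corpus$dags[[b]]
  if (is.null(da)) stop(sprintf("disease absent from corpus: '%s'", a))
  if (is.null(db)) stop(sprintf("disease absent from corpus: '%s'", b))
  dva <- semantic_value(da, corpus, base = base)
  dvb <- semantic_value(db, corpus, base = base)
  if (dva + dvb == 0) {
    warning(sprintf(
      "degenerate semantic values DV(%s)+DV(%s)=0; returning %d", a, b,
      as.integer(a == b)))
    return(as.numeric(a == b))
  }
  shared <- intersect(da$nodes, db$nodes)
  # contribution is corpus-level (independent of the DAG), so each shared
  # term contributes twice: once from each side
  2 * sum(term_contribution(shared, corpus, base = base)) / (dva + dvb)
}

#' Pairwise semantic similarity matrix over a disease subset
#'
#' Computes \code{SS} over the diseases that carry ontology annotation (the
#' set \code{IS}); diseases outside the corpus cannot appear here and fall
#' back to kernel similarity during integration.
#'
#' @param corpus a \code{\link{dag_corpus}}.
#' @param diseases subset of corpus diseases (default: all of them).
#' @param base logarithm base.
#' @return a \code{\link{similarity_matrix}} with role \code{"SS"}; the
#'   diagonal is 1 (including degenerate zero-semantic-value diseases, with
#'   a warning).
#' @export
semantic_similarity_matrix <- function(corpus,
                                       diseases = names(corpus$dags),
                                       base = exp(1)) {
  diseases <- as.character(diseases)
  missing <- setdiff(diseases, names(corpus$dags))
  if (length(missing) > 0)
    stop(sprintf("disease(s) absent from corpus: %s",
                 paste(missing, collapse = ", ")))
  n <- length(diseases)
  if (n == 0)
    return(similarity_matrix(matrix(0, 0, 0), ids = character(0), role = "SS"))

  contrib <- stats::setNames(
    term_contribution(names(corpus$term_dag_count), corpus, base = base),
    names(corpus$term_dag_count))
  node_sets <- lapply(corpus$dags[diseases], function(d) d$nodes)
  dv <- vapply(node_sets, function(nd) sum(contrib[nd]), numeric(1))

  S <- matrix(0, n, n, dimnames = list(diseases, diseases))
  degenerate <- FALSE
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      den <- dv[i] + dv[j]
      if (den == 0) {
        degenerate <- TRUE
        next
      }
      shared <- intersect(node_sets[[i]], node_sets[[j]])
      S[i, j] <- S[j, i] <- 2 * sum(contrib[shared]) / den
    }
  }
  diag(S) <- 1
  if (degenerate || any(dv == 0))
    warning("degenerate zero semantic values present; affected diagonal set to 1, off-diagonals to 0")
  similarity_matrix(S, role = "SS")
}

#' Load an ontology edge list and disease-to-term mapping
#'
#' @param edges_path TSV with columns parent term id, child term id.
#' @param mapping_path optional TSV with columns disease id, term id;
#'   diseases absent from the mapping have no semantic similarity.
#' @return list with \code{edges} and (possibly NULL) \code{map} data frames.
#' @export
load_ontology <- function(edges_path, mapping_path = NULL) {
  edges <- utils::read.delim(edges_path, header = TRUE,
                             colClasses = "character")
  names(edges)[1:2] <- c("parent", "child")
  map <- NULL
  if (!is.null(mapping_path)) {
    map <- utils::read.delim(mapping_path, header = TRUE,
                             colClasses = "character")
    names(map)[1:2] <- c("disease_id", "term_id")
  }
  list(edges = edges, map = map)
}
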