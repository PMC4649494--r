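# shared builders and independent oracles for the test suite

# association table with duplicate evidences: {(L1,D1) x2, (L2,D1), (L2,D2), (L3,D2)}
write_dedup_table <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("L1\tD1\tpcr", "L1\tD1\tmicroarray", "L2\tD1",
               "L2\tD2", "L3\tD2"), path)
  path
}

make_net <- function(A, lnc = NULL, dis = NULL) {
  if (is.null(lnc)) lnc <- sprintf("L%d", seq_len(nrow(A)))
  if (is.null(dis)) dis <- sprintf("D%d", seq_len(ncol(A)))
  association_network(lnc, dis, A)
}

# the 2-disease kernel worked example: profiles (1,0) and (1,1)
kernel_example_net <- function() {
  make_net(rbind(c(1, 1), c(0, 1)))
}

# strip similarity_matrix class/attrs for plain-matrix comparisons
unclass_m <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

# --- independent walk-enumeration oracle -------------------------------
# sum over explicit walks of length `len` from u to v, product of edge
# weights along each walk; recursion over intermediate vertices, no matrix
# algebra shared with the implementation
walk_sum_oracle <- function(M, u, v, len) {
  if (len == 1) return(M[u, v])
  total <- 0
  for (x in seq_len(nrow(M))) {
    if (M[u, x] != 0)
      total <- total + M[u, x] * walk_sum_oracle(M, x, v, len - 1)
  }
  total
}

katz_entry_oracle <- function(M, u, v, beta, k) {
  sum(vapply(seq_len(k), function(l) beta^l * walk_sum_oracle(M, u, v, l),
             numeric(1)))
}

# --- independent semantic-similarity oracle ----------------------------
# ancestor closure by iterative frontier expansion over the raw edge list
ancestors_oracle <- function(terms, edges) {
  nodes <- unique(terms)
  repeat {
    parents <- unique(edges$parent[edges$child %in% nodes])
    new <- setdiff(parents, nodes)
    if (length(new) == 0) break
    nodes <- c(nodes, new)
  }
  sort(nodes)
}

ss_oracle <- function(a_terms, b_terms, all_disease_terms, edges) {
  sets <- lapply(all_disease_terms, ancestors_oracle, edges = edges)
  n <- length(sets)
  contrib <- function(t) {
    cnt <- sum(vapply(sets, function(s) t %in% s, logical(1)))
    -log(cnt / n)
  }
  da <- ancestors_oracle(a_terms, edges)
  db <- ancestors_oracle(b_terms, edges)
  dva <- sum(vapply(da, contrib, numeric(1)))
  dvb <- sum(vapply(db, contrib, numeric(1)))
  if (dva + dvb == 0) return(as.numeric(identical(sort(a_terms), sort(b_terms))))
  shared <- intersect(da, db)
  num <- sum(vapply(shared, function(t) 2 * contrib(t), numeric(1)))
  num / (dva + dvb)
}

# --- pairwise-ordering AUC oracle --------------------------------------
# fraction of (positive, candidate) comparisons the positive wins, ties 1/2
auc_pairwise_oracle <- function(pos_scores, cand_score_list) {
  per <- mapply(function(s, cand) {
    (sum(s > cand) + 0.5 * sum(s == cand)) / length(cand)
  }, pos_scores, cand_score_list)
  mean(per)
}
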