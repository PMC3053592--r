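# Wang-method semantic similarity between GO terms and between genes'
# annotation sets. A focal term A induces its ancestor closure DAG_A; the
# semantic contribution of t in DAG_A is S_A(A) = 1 and
# S_A(t) = max over children t' of t within DAG_A of w_e * S_A(t'),
# where w_e is the relation weight of the edge t' -> t.

#' Ancestor closure of a term
#'
#' The term itself plus every term reachable by following parent edges.
#'
#' @param dag a `GoDAG`.
#' @param a term id.
#' @return character vector of term ids.
#' @export
go_ancestors <- function(dag, a) {
  if (!a %in% dag$terms)
    stop_chromex("unknown term '", a, "'", class = "chromex_lookup_error")
  seen <- character()
  queue <- a
  while (length(queue)) {
    t0 <- queue[[1L]]; queue <- queue[-1L]
    if (t0 %in% seen) next
    seen <- c(seen, t0)
    queue <- c(queue, dag$parents_of[[t0]] %||% character())
  }
  seen
}

#' Semantic contributions of a term's ancestor closure
#'
#' Fixed point of the Wang recursion over the acyclic closure. Deterministic;
#' every value lies in `(0, 1]` with `S[a] == 1`.
#'
#' @param dag a `GoDAG`.
#' @param a focal term id.
#' @return named numeric vector of S-values over the closure of `a`.
#' @export
go_s_values <- function(dag, a) {
  closure <- go_ancestors(dag, a)
  s <- stats::setNames(rep(0, length(closure)), closure)
  s[[a]] <- 1
  edges <- dag$edges[dag$edges$child %in% closure &
                       dag$edges$parent %in% closure, , drop = FALSE]
  w <- unname(dag$weights[edges$relation])
  # Bellman-Ford style relaxation; terminates because the closure is acyclic
  # (longest path bounds the number of productive sweeps).
  repeat {
    cand <- w * s[edges$child]
    upd <- cand > s[edges$parent] + 1e-15
    if (!any(upd)) break
    new_s <- tapply(cand[upd], edges$parent[upd], max)
    s[names(new_s)] <- pmax(s[names(new_s)], new_s)
  }
  s
}

#' Wang similarity of two GO terms
#'
#' `sum over shared ancestors t of (S_A(t) + S_B(t))` divided by
#' `SV(A) + SV(B)` where `SV` is the sum of a term's S-values.
#'
#' @param dag a `GoDAG`.
#' @param a,b term ids.
#' @return scalar in `(0, 1]`; symmetric; 1 for `a == b`.
#' @export
go_term_similarity <- function(dag, a, b) {
  sa <- go_s_values(dag, a)
  sb <- go_s_values(dag, b)
  shared <- intersect(names(sa), names(sb))
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

# All-pairs Wang similarity over a fixed term universe; one go_s_values call
# per term. Used by the pipeline to score thousands of gene pairs.
go_term_similarity_matrix <- function(dag, terms) {
  terms <- unique(terms)
  svals <- lapply(terms, function(t0) go_s_values(dag, t0))
  names(svals) <- terms
  sv <- vapply(svals, sum, numeric(1))
  n <- length(terms)
  out <- matrix(1, n, n, dimnames = list(terms, terms))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      sa <- svals[[i]]; sb <- svals[[j]]
      shared <- intersect(names(sa), names(sb))
      val <- sum(sa[shared] + sb[shared]) / (sv[[i]] + sv[[j]])
      out[i, j] <- val; out[j, i] <- val
    }
  }
  out
}

#' Best-match-average gene functional similarity
#'
#' For the matrix of Wang term similarities between the two genes' annotation
#' sets, the average of the row maxima together with the column maxima (BMA).
#'
#' @param dag a `GoDAG`.
#' @param ann a `GeneGoAnnotation`.
#' @param gene_a,gene_b gene ids.
#' @param combine combination rule; only `"BMA"` is provided.
#' @return scalar in `(0, 1]`, or `NA` when either gene has no annotation.
#' @export
go_gene_similarity <- function(dag, ann, gene_a, gene_b, combine = "BMA") {
  combine <- match.arg(combine, "BMA")
  ta <- ann[[gene_a]]; tb <- ann[[gene_b]]
  if (is.null(ta) || is.null(tb) || !length(ta) || !length(tb))
    return(NA_real_)
  sm <- go_term_similarity_matrix(dag, union(ta, tb))[ta, tb, drop = FALSE]
  bma_combine(sm)
}

bma_combine <- function(sim) {
  mean(c(apply(sim, 1L, max), apply(sim, 2L, max)))
}
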