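# Independent brute-force oracles and random generators used across the
# suite. These deliberately avoid the package's own query paths: everything
# is a plain loop over the raw triple rows.

# linear-scan triple matcher
brute_match <- function(kb, s = NULL, p = NULL, o = NULL) {
  tr <- kb$triples
  hits <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    ok <- TRUE
    if (!is.null(s) && !(tr$subject[i] %in% s)) ok <- FALSE
    if (!is.null(p) && !(tr$predicate[i] %in% p)) ok <- FALSE
    if (!is.null(o) && !(tr$object[i] %in% o)) ok <- FALSE
    hits[i] <- ok
  }
  out <- tr[hits, , drop = FALSE]
  rownames(out) <- NULL
  out
}

brute_objects <- function(kb, subjects, predicate) {
  tr <- kb$triples
  out <- character()
  for (i in seq_len(nrow(tr)))
    if (tr$predicate[i] == predicate && tr$subject[i] %in% subjects)
      out <- c(out, tr$object[i])
  sort(unique(out), method = "radix")
}

brute_disorders_for <- function(kb, signs) brute_objects(kb, signs, "epo:suggests")
brute_signs_of <- function(kb, disorders) brute_objects(kb, disorders, "epo:has_sign")
brute_pending <- function(kb, identified, absent = character()) {
  setdiff(brute_signs_of(kb, brute_disorders_for(kb, identified)),
          c(identified, absent))
}
brute_views_for <- function(kb, signs) brute_objects(kb, signs, "epo:requires_view")

# tally of identified signs per suggested disorder, by explicit loops
brute_differential <- function(kb, identified) {
  ds <- brute_disorders_for(kb, identified)
  res <- list()
  for (d in ds) {
    assoc <- brute_signs_of(kb, d)
    res[[d]] <- c(support = length(intersect(assoc, identified)),
                  total = length(assoc))
  }
  res
}

# random valid KB: every sign has >= 1 view, every disorder >= 1 sign
random_kb <- function(seed) {
  set.seed(seed)
  n_signs <- sample(3:8, 1)
  n_dis <- sample(2:5, 1)
  n_views <- sample(2:5, 1)
  kb <- kb_new()
  signs <- sprintf("epo:s%02d", seq_len(n_signs))
  disorders <- sprintf("epo:d%02d", seq_len(n_dis))
  views <- sprintf("epo:v%02d", seq_len(n_views))
  for (s in signs) kb <- kb_declare(kb, s, "sign", paste("sign", s))
  for (d in disorders) kb <- kb_declare(kb, d, "disorder", paste("disorder", d))
  for (v in views) kb <- kb_declare(kb, v, "echographic_view", paste("view", v))
  for (s in signs)
    for (v in sample(views, sample(1:min(2, n_views), 1)))
      kb <- kb_relate(kb, s, "epo:requires_view", v)
  for (d in disorders)
    for (s in sample(signs, sample(1:min(4, n_signs), 1)))
      kb <- kb_relate(kb, d, "epo:has_sign", s)
  kb
}

random_sign_subset <- function(kb, seed) {
  set.seed(seed)
  signs <- kb_entities(kb, "sign")$iri
  sample(signs, sample(0:length(signs), 1))
}

# two-sided p value of a t statistic by numerical integration of the t density
quadrature_t_p <- function(t_stat, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t_stat), Inf,
                       rel.tol = 1e-10)$value
}

# exact binomial lower tail by explicit enumeration with choose()
enum_mcnemar <- function(b, c) {
  n <- b + c
  k <- min(b, c)
  tail_p <- sum(choose(n, 0:k)) / 2^n
  min(1, 2 * tail_p)
}

# weighted kappa from an explicitly built contingency table
hand_weighted_kappa <- function(r1, r2, categories, weights) {
  k <- length(categories)
  tab <- matrix(0, k, k)
  for (i in seq_along(r1)) {
    a <- which(categories == r1[i]); b <- which(categories == r2[i])
    tab[a, b] <- tab[a, b] + 1
  }
  tab <- tab / sum(tab)
  w <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    d <- abs(a - b) / (k - 1)
    w[a, b] <- if (weights == "linear") d else d^2
  }
  e <- outer(rowSums(tab), colSums(tab))
  1 - sum(w * tab) / sum(w * e)
}

# all diagnosis statements over the small finite domain
all_diagnoses <- function() {
  out <- list(diagnosis("intrauterine"), diagnosis("pregnancy_of_unknown_location"))
  for (site in ectopic_sites()) out[[length(out) + 1L]] <- diagnosis("ectopic", site)
  out[[length(out) + 1L]] <- diagnosis("ectopic")
  out
}
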