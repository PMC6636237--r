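#' @title Clinical reasoning over the semiology graph
#'
#' @description
#' The reasoning principle behind the scan assistant is a four-step walk of
#' the knowledge graph, triggered each time a sign is identified in an
#' echographic view:
#' 1. list all disorders suggested by the identified signs;
#' 2. for those disorders, list all associated signs;
#' 3. subtract the signs already identified (and those assessed absent) to
#'    obtain the signs still pending;
#' 4. suggest the echographic views required to look for the pending signs,
#'    as an ordered personalized imaging protocol.
#'
#' All operations are pure set computations over the triple store and are
#' deterministic: outputs are sorted by IRI byte order, and protocol items are
#' ordered most-informative-first (see [personalized_protocol()]).
#'
#' @name protocol_reasoner
NULL

.check_declared <- function(kb, iris, kind) {
  if (length(iris) == 0L) return(invisible(iris))
  declared <- kb$kind_index[[kind]]
  if (is.null(declared)) declared <- character()
  bad <- setdiff(iris, declared)
  if (length(bad) > 0L)
    stop(sprintf("unknown %s: %s", kind, paste(bad, collapse = ", ")),
         call. = FALSE)
  invisible(iris)
}

#' Disorders suggested by a set of identified signs
#'
#' @param kb An `epo_kb` object.
#' @param identified_signs Character vector of sign IRIs.
#' @return Sorted character vector of disorder IRIs (union of `epo:suggests`
#'   objects over the identified signs).
#' @export
#' @examples
#' disorders_for(fig5_kb(), "epo:sign_A")
disorders_for <- function(kb, identified_signs) {
  identified_signs <- unique(as.character(identified_signs))
  .check_declared(kb, identified_signs, "sign")
  .kb_objects(kb, identified_signs, "epo:suggests")
}

#' Signs associated with a set of disorders
#'
#' @param kb An `epo_kb` object.
#' @param disorders Character vector of disorder IRIs.
#' @return Sorted character vector of sign IRIs (union of `epo:has_sign`
#'   objects over the disorders).
#' @export
signs_of <- function(kb, disorders) {
  disorders <- unique(as.character(disorders))
  .check_declared(kb, disorders, "disorder")
  .kb_objects(kb, disorders, "epo:has_sign")
}

#' Signs still pending for the differential diagnosis
#'
#' All signs associated with the disorders suggested by the identified signs,
#' minus the signs already identified and those the operator has assessed as
#' absent.
#'
#' @param kb An `epo_kb` object.
#' @param identified_signs Character vector of sign IRIs found so far.
#' @param absent_signs Character vector of sign IRIs searched for and not
#'   found; these are retired from the pending set.
#' @return Sorted character vector of pending sign IRIs.
#' @export
#' @examples
#' pending_signs(fig5_kb(), "epo:sign_A")
pending_signs <- function(kb, identified_signs, absent_signs = character()) {
  identified_signs <- unique(as.character(identified_signs))
  absent_signs <- unique(as.character(absent_signs))
  .check_declared(kb, absent_signs, "sign")
  all_signs <- signs_of(kb, disorders_for(kb, identified_signs))
  setdiff(all_signs, c(identified_signs, absent_signs))
}

#' Echographic views required to demonstrate a set of signs
#'
#' @param kb An `epo_kb` object.
#' @param signs Character vector of sign IRIs.
#' @return Sorted character vector of echographic-view IRIs (union of
#'   `epo:requires_view` objects).
#' @export
views_for <- function(kb, signs) {
  signs <- unique(as.character(signs))
  .check_declared(kb, signs, "sign")
  .kb_objects(kb, signs, "epo:requires_view")
}

#' Derive the personalized imaging protocol
#'
#' One protocol item per echographic view that (a) is required by at least
#' one pending sign and (b) has not already been completed. Each item carries
#' the pending signs to seek in that view. Items are ordered
#' most-informative-first: descending number of sought signs, ties broken by
#' ascending view label, then view IRI; ranks run 1..n without gaps.
#'
#' @param kb An `epo_kb` object.
#' @param identified_signs Sign IRIs found so far.
#' @param completed_views View IRIs already acquired; excluded from the
#'   protocol.
#' @param absent_signs Sign IRIs assessed absent; retired from the pending
#'   set.
#' @return An object of class `imaging_protocol`: a list of items, each with
#'   elements `rank`, `view`, `view_label` and `sought_signs`.
#' @export
#' @examples
#' personalized_protocol(fig5_kb(), "epo:sign_A")
personalized_protocol <- function(kb, identified_signs,
                                  completed_views = character(),
                                  absent_signs = character()) {
  completed_views <- unique(as.character(completed_views))
  .check_declared(kb, completed_views, "echographic_view")
  pend <- pending_signs(kb, identified_signs, absent_signs)
  views <- setdiff(views_for(kb, pend), completed_views)
  items <- lapply(views, function(v) {
    tr <- kb$triples
    seekers <- tr$subject[tr$predicate == "epo:requires_view" & tr$object == v]
    list(view = v, sought_signs = sort(intersect(pend, seekers), method = "radix"))
  })
  items <- Filter(function(it) length(it$sought_signs) > 0L, items)
  if (length(items) > 0L) {
    ents <- kb_entities(kb)
    labels <- vapply(items, function(it) {
      lab <- ents$label[match(it$view, ents$iri)]
      if (is.na(lab)) it$view else lab
    }, character(1))
    n_sought <- vapply(items, function(it) length(it$sought_signs), integer(1))
    iris <- vapply(items, `[[`, character(1), "view")
    ord <- order(-n_sought, labels, iris, method = "radix")
    items <- items[ord]
    for (i in seq_along(items)) {
      items[[i]]$rank <- i
      items[[i]]$view_label <- labels[ord][i]
    }
  }
  structure(items, class = "imaging_protocol")
}

#' @export
print.imaging_protocol <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<imaging_protocol> complete: no pending views\n")
    return(invisible(x))
  }
  cat(sprintf("<imaging_protocol> %d view(s) to acquire\n", length(x)))
  for (it in x)
    cat(sprintf("  %d. %s  [seek: %s]\n", it$rank, it$view_label,
                paste(it$sought_signs, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.imaging_protocol <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(rank = integer(), view = character(),
                      view_label = character(), n_sought = integer(),
                      sought_signs = character(), stringsAsFactors = FALSE))
  data.frame(
    rank = vapply(x, `[[`, integer(1), "rank"),
    view = vapply(x, `[[`, character(1), "view"),
    view_label = vapply(x, `[[`, character(1), "view_label"),
    n_sought = vapply(x, function(it) length(it$sought_signs), integer(1)),
    sought_signs = vapply(x, function(it) paste(it$sought_signs, collapse = ";"),
                          character(1)),
    stringsAsFactors = FALSE
  )
}

#' Ranked differential diagnosis
#'
#' One row per disorder suggested by the identified signs, with the number of
#' identified supporting signs (`support`), the total number of signs
#' associated with the disorder (`total_signs`) and their ratio
#' (`completeness`). Rows are ordered by descending support, then descending
#' completeness, then label, then IRI. The ranking is an explicit artifact
#' convention: simplest defensible evidence ordering.
#'
#' @param kb An `epo_kb` object.
#' @param identified_signs Sign IRIs found so far.
#' @return Data frame with columns `disorder`, `label`, `support`,
#'   `total_signs`, `completeness`.
#' @export
#' @examples
#' differential(fig5_kb(), "epo:sign_A")
differential <- function(kb, identified_signs) {
  identified_signs <- unique(as.character(identified_signs))
  ds <- disorders_for(kb, identified_signs)
  if (length(ds) == 0L)
    return(data.frame(disorder = character(), label = character(),
                      support = integer(), total_signs = integer(),
                      completeness = numeric(), stringsAsFactors = FALSE))
  ents <- kb_entities(kb)
  support <- integer(length(ds))
  total <- integer(length(ds))
  for (i in seq_along(ds)) {
    assoc <- .kb_objects(kb, ds[i], "epo:has_sign")
    total[i] <- length(assoc)
    support[i] <- length(intersect(assoc, identified_signs))
  }
  labels <- ents$label[match(ds, ents$iri)]
  labels[is.na(labels)] <- ds[is.na(labels)]
  out <- data.frame(disorder = ds, label = labels, support = support,
                    total_signs = total, completeness = support / total,
                    stringsAsFactors = FALSE)
  ord <- order(-out$support, -out$completeness, out$label, out$disorder,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
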