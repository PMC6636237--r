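#' @title Knowledge base of early-pregnancy ultrasound semiology
#'
#' @description
#' A knowledge base (`epo_kb`) is a set of subject--predicate--object triples
#' over a small, fixed vocabulary describing ultrasound semiology: signs,
#' disorders, echographic views, anatomical structures, ultrasound routes and
#' modes, plus their SKOS labels and definitions. The canonical relation
#' direction is `epo:has_sign` (disorder to sign); its inverse `epo:suggests`
#' (sign to disorder) is materialized automatically so both query directions
#' are always available.
#'
#' @details
#' Entities are declared with [kb_declare()] (which records `epo:kind` and
#' `skos:prefLabel`) and related with [kb_relate()]. The store keeps triples
#' deduplicated and sorted by subject, predicate, object (byte order), so
#' every derived output is reproducible bit for bit.
#'
#' @name epo_kb
NULL

## Fixed vocabulary ----------------------------------------------------------

.kb_default_prefixes <- function() {
  c(epo  = "http://purl.example.org/epo#",
    skos = "http://www.w3.org/2004/02/skos/core#")
}

# predicates taking an IRI object, with their expected subject/object kinds
.kb_iri_predicates <- function() {
  list(
    "epo:suggests"      = list(subject = "sign",     object = "disorder"),
    "epo:has_sign"      = list(subject = "disorder", object = "sign"),
    "epo:requires_view" = list(subject = "sign",     object = "echographic_view"),
    "epo:located_in"    = list(subject = c("sign", "anatomical_structure"),
                               object = "anatomical_structure")
  )
}

.kb_literal_predicates <- function() {
  c("skos:prefLabel", "epo:kind", "epo:definition", "epo:reference_image")
}

.kb_predicates <- function() {
  c(names(.kb_iri_predicates()), .kb_literal_predicates())
}

#' Entity kinds recognized by the knowledge base
#' @return Character vector of valid `epo:kind` values.
#' @export
kb_kinds <- function() {
  c("sign", "disorder", "echographic_view", "anatomical_structure",
    "ultrasound_route", "ultrasound_mode")
}

.empty_triples <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), literal = logical(),
             stringsAsFactors = FALSE)
}

## Construction --------------------------------------------------------------

#' Create an empty knowledge base
#'
#' @param prefixes Named character vector of extra prefix declarations
#'   (names are prefixes, values namespace IRIs). The `epo` and `skos`
#'   prefixes are always declared.
#' @return An object of class `epo_kb`.
#' @export
#' @examples
#' kb <- kb_new()
#' kb <- kb_declare(kb, "epo:sign_A", "sign", "sign A")
kb_new <- function(prefixes = NULL) {
  pfx <- .kb_default_prefixes()
  if (!is.null(prefixes)) {
    stopifnot(is.character(prefixes), !is.null(names(prefixes)))
    pfx <- c(pfx, prefixes[setdiff(names(prefixes), names(pfx))])
  }
  kb <- structure(list(prefixes = pfx, triples = .empty_triples(),
                       entities = NULL),
                  class = "epo_kb")
  .kb_canonicalize(kb)
}

.is_pname <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_][A-Za-z0-9_.-]*$", x)
}

.kb_check_iri <- function(kb, iri, what = "IRI") {
  if (length(iri) != 1L || !is.character(iri) || is.na(iri) || !nzchar(iri))
    stop(what, " must be a single nonempty string", call. = FALSE)
  if (!.is_pname(iri))
    stop(sprintf("malformed %s: '%s' (expected prefix:localname)", what, iri),
         call. = FALSE)
  pfx <- sub(":.*$", "", iri)
  if (!pfx %in% names(kb$prefixes))
    stop(sprintf("undeclared prefix '%s' in %s '%s'", pfx, what, iri),
         call. = FALSE)
  invisible(iri)
}

.kb_add_triple <- function(kb, subject, predicate, object, literal) {
  kb$triples <- rbind(kb$triples,
                      data.frame(subject = subject, predicate = predicate,
                                 object = object, literal = literal,
                                 stringsAsFactors = FALSE))
  kb
}

# dedupe, materialize the suggests/has_sign inverse closure, sort, and
# rebuild the entity cache; every public constructor funnels through here
.kb_canonicalize <- function(kb) {
  tr <- kb$triples
  hs <- tr[tr$predicate == "epo:has_sign", , drop = FALSE]
  sg <- tr[tr$predicate == "epo:suggests", , drop = FALSE]
  if (nrow(hs) > 0L)
    tr <- rbind(tr, data.frame(subject = hs$object, predicate = "epo:suggests",
                               object = hs$subject, literal = FALSE,
                               stringsAsFactors = FALSE))
  if (nrow(sg) > 0L)
    tr <- rbind(tr, data.frame(subject = sg$object, predicate = "epo:has_sign",
                               object = sg$subject, literal = FALSE,
                               stringsAsFactors = FALSE))
  tr <- unique(tr)
  ord <- order(tr$subject, tr$predicate, tr$object, method = "radix")
  tr <- tr[ord, , drop = FALSE]
  rownames(tr) <- NULL
  kb$triples <- tr
  kb$entities <- .kb_build_entities(tr)
  kb$kind_index <- split(kb$entities$iri, kb$entities$kind)
  kb
}

.kb_build_entities <- function(tr) {
  kinds <- tr[tr$predicate == "epo:kind", , drop = FALSE]
  if (nrow(kinds) == 0L)
    return(data.frame(iri = character(), kind = character(),
                      label = character(), definition = character(),
                      stringsAsFactors = FALSE))
  labels <- tr[tr$predicate == "skos:prefLabel", , drop = FALSE]
  defs <- tr[tr$predicate == "epo:definition", , drop = FALSE]
  data.frame(
    iri = kinds$subject,
    kind = kinds$object,
    label = labels$object[match(kinds$subject, labels$subject)],
    definition = defs$object[match(kinds$subject, defs$subject)],
    stringsAsFactors = FALSE
  )
}

#' Declare an entity in the knowledge base
#'
#' Records the entity's kind (`epo:kind`), preferred label
#' (`skos:prefLabel`), and optionally a text definition and opaque reference
#' image identifiers.
#'
#' @param kb An `epo_kb` object.
#' @param iri Entity IRI as `prefix:localname`.
#' @param kind One of [kb_kinds()].
#' @param label Nonempty preferred label.
#' @param definition Optional definition text.
#' @param reference_images Character vector of opaque image references.
#' @return The updated `epo_kb`.
#' @export
kb_declare <- function(kb, iri, kind, label, definition = NULL,
                       reference_images = character()) {
  stopifnot(inherits(kb, "epo_kb"))
  .kb_check_iri(kb, iri, "entity IRI")
  kind <- match.arg(kind, kb_kinds())
  if (!is.character(label) || length(label) != 1L || is.na(label) || !nzchar(label))
    stop("pref_label must be a nonempty string", call. = FALSE)
  kb <- .kb_add_triple(kb, iri, "epo:kind", kind, TRUE)
  kb <- .kb_add_triple(kb, iri, "skos:prefLabel", label, TRUE)
  if (!is.null(definition))
    kb <- .kb_add_triple(kb, iri, "epo:definition", definition, TRUE)
  for (img in reference_images)
    kb <- .kb_add_triple(kb, iri, "epo:reference_image", img, TRUE)
  .kb_canonicalize(kb)
}

#' Add a domain relation between two entities
#'
#' The inverse closure between `epo:has_sign` and `epo:suggests` is
#' materialized automatically, so adding either direction yields both.
#'
#' @param kb An `epo_kb` object.
#' @param subject,object Entity IRIs.
#' @param predicate One of `epo:has_sign`, `epo:suggests`,
#'   `epo:requires_view`, `epo:located_in`.
#' @return The updated `epo_kb`.
#' @export
kb_relate <- function(kb, subject, predicate, object) {
  stopifnot(inherits(kb, "epo_kb"))
  if (!predicate %in% names(.kb_iri_predicates()))
    stop(sprintf("'%s' is not a declared object-property predicate", predicate),
         call. = FALSE)
  .kb_check_iri(kb, subject, "subject")
  .kb_check_iri(kb, object, "object")
  kb <- .kb_add_triple(kb, subject, predicate, object, FALSE)
  .kb_canonicalize(kb)
}

## Query ---------------------------------------------------------------------

#' Match triples against a subject/predicate/object pattern
#'
#' `NULL` in any position is a wildcard. Results are returned in the store's
#' canonical order (sorted by subject, predicate, object).
#'
#' @param kb An `epo_kb` object.
#' @param subject,predicate,object Pattern positions; `NULL` matches anything.
#' @return A data frame of matching triples with columns `subject`,
#'   `predicate`, `object`, `literal`.
#' @export
#' @examples
#' kb <- fig5_kb()
#' kb_match(kb, subject = "epo:sign_A", predicate = "epo:suggests")
kb_match <- function(kb, subject = NULL, predicate = NULL, object = NULL) {
  stopifnot(inherits(kb, "epo_kb"))
  tr <- kb$triples
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(subject))   keep <- keep & tr$subject %in% subject
  if (!is.null(predicate)) keep <- keep & tr$predicate %in% predicate
  if (!is.null(object))    keep <- keep & tr$object %in% object
  out <- tr[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# sorted unique objects of `predicate` over a set of subjects
.kb_objects <- function(kb, subjects, predicate) {
  if (length(subjects) == 0L) return(character())
  tr <- kb$triples
  hit <- tr$predicate == predicate & tr$subject %in% subjects
  sort(unique(tr$object[hit]), method = "radix")
}

#' Declared entities of a knowledge base
#'
#' @param kb An `epo_kb` object.
#' @param kind Optional filter on entity kind.
#' @return Data frame with columns `iri`, `kind`, `label`, `definition`.
#' @export
kb_entities <- function(kb, kind = NULL) {
  stopifnot(inherits(kb, "epo_kb"))
  ents <- kb$entities
  if (!is.null(kind)) ents <- ents[ents$kind %in% kind, , drop = FALSE]
  rownames(ents) <- NULL
  ents
}

#' Export declared entities as JSON
#'
#' @param kb An `epo_kb` object.
#' @param file Optional path; when given, the JSON is also written there.
#' @return JSON text (invisibly when `file` is given).
#' @export
kb_entities_json <- function(kb, file = NULL) {
  txt <- jsonlite::toJSON(kb_entities(kb), dataframe = "rows", na = "null",
                          auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @export
print.epo_kb <- function(x, ...) {
  ents <- kb_entities(x)
  cat(sprintf("<epo_kb> %d triples, %d entities\n", nrow(x$triples), nrow(ents)))
  if (nrow(ents) > 0L)
    print(table(kind = ents$kind))
  invisible(x)
}

## Turtle serialization ------------------------------------------------------

.ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub('"', '\\"', x, fixed = TRUE)
}

.ttl_unescape <- function(x) {
  x <- gsub('\\"', '"', x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

#' Serialize a knowledge base to Turtle
#'
#' The dialect is deliberately small: `@prefix` declarations, one
#' subject--predicate--object statement per line, and plain string literals.
#' Output is deterministic (prefixes sorted by name, triples in canonical
#' store order), so [load_turtle()] of the result reproduces the knowledge
#' base exactly.
#'
#' @param kb An `epo_kb` object.
#' @param file Optional path to write to.
#' @return The Turtle document as a single string.
#' @export
save_turtle <- function(kb, file = NULL) {
  stopifnot(inherits(kb, "epo_kb"))
  pfx <- kb$prefixes[order(names(kb$prefixes), method = "radix")]
  head <- sprintf("@prefix %s: <%s> .", names(pfx), unname(pfx))
  tr <- kb$triples
  obj <- ifelse(tr$literal, sprintf('"%s"', .ttl_escape(tr$object)), tr$object)
  body <- sprintf("%s %s %s .", tr$subject, tr$predicate, obj)
  txt <- paste(c(head, "", body), collapse = "\n")
  txt <- paste0(txt, "\n")
  if (!is.null(file)) {
    cat(txt, file = file)
    return(invisible(txt))
  }
  txt
}

#' Load a knowledge base from Turtle
#'
#' Parses the minimal Turtle dialect written by [save_turtle()]: `@prefix`
#' declarations, simple one-line statements, string literals, full-line `#`
#' comments. Duplicate statements are collapsed and the
#' `epo:has_sign`/`epo:suggests` inverse closure is materialized.
#'
#' @param x Turtle text (single string or character vector of lines), or the
#'   path of a `.ttl` file.
#' @return An `epo_kb` object.
#' @export
#' @examples
#' kb <- load_turtle(save_turtle(fig5_kb()))
load_turtle <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    x <- readLines(x, warn = FALSE)
  lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  prefixes <- character()
  rows <- vector("list", length(lines))
  iri_preds <- names(.kb_iri_predicates())
  lit_preds <- .kb_literal_predicates()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    m <- regmatches(line,
      regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9_.-]*):\\s*<([^>]*)>\\s*\\.$", line))[[1]]
    if (length(m) == 3L) {
      prefixes[m[2]] <- m[3]
      next
    }
    m <- regmatches(line,
      regexec('^(\\S+)\\s+(\\S+)\\s+(.+?)\\s*\\.$', line))[[1]]
    if (length(m) != 4L)
      stop(sprintf("Turtle parse error at line %d: '%s'", i, line), call. = FALSE)
    s <- m[2]; p <- m[3]; o <- m[4]
    for (term in c(s, p)) {
      if (!.is_pname(term))
        stop(sprintf("Turtle parse error at line %d: malformed name '%s'", i, term),
             call. = FALSE)
      if (!sub(":.*$", "", term) %in% names(prefixes))
        stop(sprintf("line %d: undeclared prefix in '%s'", i, term), call. = FALSE)
    }
    if (!p %in% .kb_predicates())
      stop(sprintf("line %d: predicate '%s' is not in the declared vocabulary", i, p),
           call. = FALSE)
    if (grepl('^".*"$', o)) {
      if (p %in% iri_preds)
        stop(sprintf("line %d: literal object where an IRI is required for '%s'", i, p),
             call. = FALSE)
      o <- .ttl_unescape(substr(o, 2L, nchar(o) - 1L))
      lit <- TRUE
    } else {
      if (!.is_pname(o))
        stop(sprintf("Turtle parse error at line %d: malformed object '%s'", i, o),
             call. = FALSE)
      if (!sub(":.*$", "", o) %in% names(prefixes))
        stop(sprintf("line %d: undeclared prefix in '%s'", i, o), call. = FALSE)
      if (p %in% lit_preds)
        stop(sprintf("line %d: IRI object where a literal is required for '%s'", i, p),
             call. = FALSE)
      lit <- FALSE
    }
    rows[[i]] <- data.frame(subject = s, predicate = p, object = o,
                            literal = lit, stringsAsFactors = FALSE)
  }
  kb <- structure(list(prefixes = prefixes,
                       triples = do.call(rbind, c(list(.empty_triples()), rows)),
                       entities = NULL),
                  class = "epo_kb")
  .kb_canonicalize(kb)
}

## Integrity validation ------------------------------------------------------

.kb_issue <- function(code, iri, detail) {
  data.frame(code = code, iri = iri, detail = detail, stringsAsFactors = FALSE)
}

#' Validate knowledge-base integrity
#'
#' Checks the structural rules every curated knowledge base must satisfy:
#' every IRI used in a domain relation is a declared, labelled entity of the
#' expected kind; the `epo:suggests`/`epo:has_sign` inverse closure holds;
#' every sign has at least one required echographic view; every disorder has
#' at least one associated sign.
#'
#' @param kb An `epo_kb` object.
#' @return A data frame of issues with columns `code`, `iri`, `detail`;
#'   zero rows when the knowledge base is valid. Issues are data, not errors.
#' @export
#' @examples
#' nrow(kb_validate(fig5_kb())) # 0
kb_validate <- function(kb) {
  stopifnot(inherits(kb, "epo_kb"))
  tr <- kb$triples
  ents <- kb$entities
  issues <- list()
  spec <- .kb_iri_predicates()

  kind_of <- function(iri) ents$kind[match(iri, ents$iri)]

  bad_kind <- ents$iri[!ents$kind %in% kb_kinds()]
  for (iri in bad_kind)
    issues[[length(issues) + 1L]] <-
      .kb_issue("invalid_kind", iri, sprintf("epo:kind '%s' not recognized", kind_of(iri)))

  no_label <- ents$iri[is.na(ents$label) | !nzchar(ents$label)]
  for (iri in no_label)
    issues[[length(issues) + 1L]] <-
      .kb_issue("entity_without_label", iri, "no skos:prefLabel")

  for (p in names(spec)) {
    rel <- tr[tr$predicate == p, , drop = FALSE]
    if (nrow(rel) == 0L) next
    for (pos in c("subject", "object")) {
      iris <- unique(rel[[pos]])
      expected <- spec[[p]][[pos]]
      undecl <- iris[!iris %in% ents$iri]
      for (iri in undecl)
        issues[[length(issues) + 1L]] <-
          .kb_issue("undeclared_entity", iri,
                    sprintf("%s of %s is not a declared entity", pos, p))
      known <- iris[iris %in% ents$iri]
      mism <- known[!kind_of(known) %in% expected]
      for (iri in mism)
        issues[[length(issues) + 1L]] <-
          .kb_issue("kind_mismatch", iri,
                    sprintf("%s of %s must have kind %s, found '%s'",
                            pos, p, paste(expected, collapse = "/"), kind_of(iri)))
    }
  }

  # inverse closure suggests(s,d) <=> has_sign(d,s)
  hs <- tr[tr$predicate == "epo:has_sign", , drop = FALSE]
  sg <- tr[tr$predicate == "epo:suggests", , drop = FALSE]
  hs_key <- paste(hs$subject, hs$object)
  sg_key <- paste(sg$object, sg$subject)
  for (k in setdiff(hs_key, sg_key)) {
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    issues[[length(issues) + 1L]] <-
      .kb_issue("inverse_closure_violation", parts[1],
                sprintf("epo:has_sign(%s, %s) lacks inverse epo:suggests", parts[1], parts[2]))
  }
  for (k in setdiff(sg_key, hs_key)) {
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    issues[[length(issues) + 1L]] <-
      .kb_issue("inverse_closure_violation", parts[2],
                sprintf("epo:suggests(%s, %s) lacks inverse epo:has_sign", parts[2], parts[1]))
  }

  signs <- ents$iri[ents$kind == "sign"]
  with_view <- unique(tr$subject[tr$predicate == "epo:requires_view"])
  for (iri in setdiff(signs, with_view))
    issues[[length(issues) + 1L]] <-
      .kb_issue("sign_without_view", iri, "sign has no epo:requires_view")

  disorders <- ents$iri[ents$kind == "disorder"]
  with_sign <- unique(tr$subject[tr$predicate == "epo:has_sign"])
  for (iri in setdiff(disorders, with_sign))
    issues[[length(issues) + 1L]] <-
      .kb_issue("disorder_without_sign", iri, "disorder has no epo:has_sign")

  out <- do.call(rbind, c(list(.kb_issue(character(), character(), character())), issues))
  ord <- order(out$code, out$iri, out$detail, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
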