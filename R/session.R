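#' @title Scan-session workflow
#'
#' @description
#' A scan session follows the assisted-examination workflow: (1) acquire
#' ultrasound images; (2) describe each image with controlled keywords
#' (anatomical structures, signs present or searched-and-absent, route, mode,
#' view); (3) query the system for guidance -- the personalized imaging
#' protocol derived from the signs identified so far; (4) finalize with a
#' structured report. Sessions are stateful objects (environments): the
#' helpers mutate them in place and two sessions never share state.
#'
#' @name scan_session
NULL

.default_clinical_info <- function() "moderate pelvic pain and positive pregnancy test"

#' Start a new scan session
#'
#' @param kb The `epo_kb` the session reasons over.
#' @param case_id Case identifier.
#' @param clinical_info Clinical context shown to the operator; defaults to
#'   the standard emergency presentation used for every study case.
#' @param started_at Optional caller-supplied timestamp (text); no wall clock
#'   is read inside the workflow, so runs are deterministic.
#' @return An object of class `scan_session`.
#' @export
#' @examples
#' s <- new_session(fig5_kb(), "case_01")
new_session <- function(kb, case_id, clinical_info = NULL, started_at = NA_character_) {
  stopifnot(inherits(kb, "epo_kb"))
  if (!is.character(case_id) || length(case_id) != 1L || !nzchar(case_id))
    stop("case_id must be a nonempty string", call. = FALSE)
  if (is.null(clinical_info)) clinical_info <- .default_clinical_info()
  s <- new.env(parent = emptyenv())
  s$kb <- kb
  s$case_id <- case_id
  s$clinical_info <- clinical_info
  s$annotations <- list()
  s$started_at <- started_at
  s$finished_at <- NA_character_
  s$finished <- FALSE
  class(s) <- "scan_session"
  s
}

#' Structured image annotation
#'
#' The controlled-keyword description of one acquired image: the echographic
#' view, the anatomical structures depicted, the signs demonstrated, the
#' signs deliberately searched for and not found, and optionally the
#' ultrasound route and mode.
#'
#' @param image_id Opaque image identifier, unique within a session.
#' @param view Echographic-view IRI.
#' @param signs_present,signs_absent Disjoint sets of sign IRIs.
#' @param structures Anatomical-structure IRIs.
#' @param route,mode Optional ultrasound route / mode IRIs.
#' @return An object of class `image_annotation`.
#' @export
image_annotation <- function(image_id, view, signs_present = character(),
                             signs_absent = character(),
                             structures = character(),
                             route = NULL, mode = NULL) {
  if (!is.character(image_id) || length(image_id) != 1L || !nzchar(image_id))
    stop("image_id must be a nonempty string", call. = FALSE)
  signs_present <- unique(as.character(signs_present))
  signs_absent <- unique(as.character(signs_absent))
  both <- intersect(signs_present, signs_absent)
  if (length(both) > 0L)
    stop(sprintf("signs cannot be both present and absent: %s",
                 paste(both, collapse = ", ")), call. = FALSE)
  structure(list(image_id = image_id, view = view,
                 signs_present = signs_present, signs_absent = signs_absent,
                 structures = unique(as.character(structures)),
                 route = route, mode = mode),
            class = "image_annotation")
}

.check_annotation <- function(kb, ann) {
  .check_declared(kb, ann$view, "echographic_view")
  .check_declared(kb, ann$signs_present, "sign")
  .check_declared(kb, ann$signs_absent, "sign")
  .check_declared(kb, ann$structures, "anatomical_structure")
  if (!is.null(ann$route)) .check_declared(kb, ann$route, "ultrasound_route")
  if (!is.null(ann$mode)) .check_declared(kb, ann$mode, "ultrasound_mode")
  invisible(ann)
}

#' Add an annotated image to a session
#'
#' Validates every keyword IRI against the session's knowledge base (an
#' undeclared IRI or a kind mismatch is an error naming the offending IRI)
#' and appends the annotation. Duplicate image identifiers are rejected.
#'
#' @param session A `scan_session`.
#' @param annotation An [image_annotation()].
#' @return The session, invisibly (mutated in place).
#' @export
add_image <- function(session, annotation) {
  stopifnot(inherits(session, "scan_session"), inherits(annotation, "image_annotation"))
  if (session$finished)
    stop("session already finalized", call. = FALSE)
  .check_annotation(session$kb, annotation)
  ids <- vapply(session$annotations, `[[`, character(1), "image_id")
  if (annotation$image_id %in% ids)
    stop(sprintf("duplicate image_id '%s'", annotation$image_id), call. = FALSE)
  session$annotations[[length(session$annotations) + 1L]] <- annotation
  invisible(session)
}

#' Signs identified so far in a session
#'
#' Union of `signs_present` over all annotations, sorted.
#' @param session A `scan_session`.
#' @return Character vector of sign IRIs.
#' @export
identified_signs <- function(session) {
  stopifnot(inherits(session, "scan_session"))
  found <- unlist(lapply(session$annotations, `[[`, "signs_present"),
                  use.names = FALSE)
  sort(unique(c(character(), found)), method = "radix")
}

#' Signs assessed absent in a session
#'
#' Union of `signs_absent` over all annotations, minus any sign also
#' recorded present elsewhere: presence is a positive observation while
#' absence is a failed search, so presence wins.
#' @param session A `scan_session`.
#' @return Character vector of sign IRIs.
#' @export
absent_signs <- function(session) {
  stopifnot(inherits(session, "scan_session"))
  ab <- unlist(lapply(session$annotations, `[[`, "signs_absent"),
               use.names = FALSE)
  ab <- sort(unique(c(character(), ab)), method = "radix")
  setdiff(ab, identified_signs(session))
}

#' Echographic views already acquired in a session
#' @param session A `scan_session`.
#' @return Character vector of view IRIs.
#' @export
completed_views <- function(session) {
  stopifnot(inherits(session, "scan_session"))
  sort(unique(vapply(session$annotations, `[[`, character(1), "view")),
       method = "radix")
}

#' Current guidance for a session
#'
#' Delegates to [personalized_protocol()] with the session's identified
#' signs, absent signs retired, and completed views excluded.
#'
#' @param session A `scan_session`.
#' @return An `imaging_protocol` (possibly empty).
#' @export
next_guidance <- function(session) {
  stopifnot(inherits(session, "scan_session"))
  personalized_protocol(session$kb,
                        identified_signs = identified_signs(session),
                        completed_views = completed_views(session),
                        absent_signs = absent_signs(session))
}

#' Finalize a session into a structured report
#'
#' @param session A `scan_session` (not yet finalized).
#' @param operator_id Operator identifier.
#' @param mode `"assisted"` or `"nonassisted"`.
#' @param conclusion A [diagnosis()] statement.
#' @param duration_min Nonnegative scan duration in minutes.
#' @param finished_at Optional caller-supplied timestamp (text).
#' @return An immutable object of class `scan_report` with the image list in
#'   acquisition order and `protocol_complete` indicating whether the
#'   guidance was empty at finalization.
#' @export
finalize_session <- function(session, operator_id, mode = c("assisted", "nonassisted"),
                             conclusion, duration_min,
                             finished_at = NA_character_) {
  stopifnot(inherits(session, "scan_session"))
  mode <- match.arg(mode)
  if (session$finished)
    stop("session already finalized", call. = FALSE)
  if (!inherits(conclusion, "diagnosis"))
    stop("conclusion must be a diagnosis() statement", call. = FALSE)
  if (!is.numeric(duration_min) || length(duration_min) != 1L ||
      is.na(duration_min) || duration_min < 0)
    stop("duration_min must be a nonnegative number", call. = FALSE)
  image_ids <- vapply(session$annotations, `[[`, character(1), "image_id")
  report <- structure(list(
    case_id = session$case_id,
    operator_id = operator_id,
    mode = mode,
    conclusion = conclusion,
    clinical_info = session$clinical_info,
    image_ids = image_ids,
    image_count = length(image_ids),
    duration_min = duration_min,
    protocol_complete = length(next_guidance(session)) == 0L,
    started_at = session$started_at,
    finished_at = finished_at
  ), class = "scan_report")
  session$finished <- TRUE
  session$finished_at <- finished_at
  report
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("<scan_report> case %s, operator %s, %s mode\n",
              x$case_id, x$operator_id, x$mode))
  cat(sprintf("  conclusion: %s\n", format(x$conclusion)))
  cat(sprintf("  images: %d, duration: %.1f min, protocol complete: %s\n",
              x$image_count, x$duration_min, x$protocol_complete))
  invisible(x)
}

#' Serialize a report to JSON
#' @param report A `scan_report`.
#' @param file Optional path to write to.
#' @return JSON text.
#' @export
report_to_json <- function(report, file = NULL) {
  stopifnot(inherits(report, "scan_report"))
  x <- unclass(report)
  x$conclusion <- list(location_class = report$conclusion$location_class,
                       ectopic_site = report$conclusion$ectopic_site)
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", na = "null",
                          pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Deserialize a report from JSON
#' @param x JSON text or a file path.
#' @return A `scan_report`.
#' @export
report_from_json <- function(x) {
  if (length(x) == 1L && !grepl("[{]", x) && file.exists(x))
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  concl <- diagnosis(obj$conclusion$location_class,
                     if (!is.null(obj$conclusion$ectopic_site))
                       obj$conclusion$ectopic_site)
  structure(list(
    case_id = obj$case_id,
    operator_id = obj$operator_id,
    mode = obj$mode,
    conclusion = concl,
    clinical_info = obj$clinical_info,
    image_ids = as.character(obj$image_ids),
    image_count = as.integer(obj$image_count),
    duration_min = as.numeric(obj$duration_min),
    protocol_complete = as.logical(obj$protocol_complete),
    started_at = if (is.null(obj$started_at)) NA_character_ else obj$started_at,
    finished_at = if (is.null(obj$finished_at)) NA_character_ else obj$finished_at
  ), class = "scan_report")
}

## Session persistence (self-contained JSON incl. the KB as Turtle) ----------

#' Serialize a session to JSON
#'
#' The knowledge base is embedded as Turtle text so the file is
#' self-contained.
#' @param session A `scan_session`.
#' @param file Optional path to write to.
#' @return JSON text.
#' @export
session_to_json <- function(session, file = NULL) {
  stopifnot(inherits(session, "scan_session"))
  anns <- lapply(session$annotations, function(a) {
    list(image_id = a$image_id, view = a$view,
         signs_present = a$signs_present, signs_absent = a$signs_absent,
         structures = a$structures, route = a$route, mode = a$mode)
  })
  x <- list(case_id = session$case_id, clinical_info = session$clinical_info,
            kb_turtle = save_turtle(session$kb), annotations = anns,
            started_at = session$started_at, finished_at = session$finished_at,
            finished = session$finished)
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", na = "null",
                          pretty = TRUE)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Deserialize a session from JSON
#' @param x JSON text or a file path.
#' @return A `scan_session`.
#' @export
session_from_json <- function(x) {
  if (length(x) == 1L && !grepl("[{]", x) && file.exists(x))
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  kb <- load_turtle(obj$kb_turtle)
  s <- new_session(kb, obj$case_id, obj$clinical_info,
                   started_at = if (is.null(obj$started_at)) NA_character_
                                else obj$started_at)
  for (a in obj$annotations) {
    ann <- image_annotation(a$image_id, a$view,
                            signs_present = unlist(a$signs_present),
                            signs_absent = unlist(a$signs_absent),
                            structures = unlist(a$structures),
                            route = a$route, mode = a$mode)
    add_image(s, ann)
  }
  s$finished <- isTRUE(obj$finished)
  s$finished_at <- if (is.null(obj$finished_at)) NA_character_ else obj$finished_at
  s
}

#' @export
print.scan_session <- function(x, ...) {
  cat(sprintf("<scan_session> case %s: %d image(s), %d sign(s) identified%s\n",
              x$case_id, length(x$annotations), length(identified_signs(x)),
              if (x$finished) " [finalized]" else ""))
  invisible(x)
}
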