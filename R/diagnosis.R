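#' Valid pregnancy location classes
#' @return Character vector of location classes.
#' @export
location_classes <- function() {
  c("intrauterine", "ectopic", "pregnancy_of_unknown_location")
}

#' Valid ectopic implantation sites
#' @return Character vector of ectopic sites.
#' @export
ectopic_sites <- function() {
  c("tubal", "interstitial", "cervical", "cesarean_scar", "ovarian",
    "abdominal", "heterotopic", "unspecified")
}

#' Structured diagnosis statement
#'
#' A report conclusion is a location class (intrauterine, ectopic, or
#' pregnancy of unknown location) plus, for ectopic pregnancies only, an
#' optional precise implantation site. Stating the precise site (e.g.
#' `"tubal"`) is what distinguishes an exact diagnosis from a merely correct
#' location diagnosis; `"unspecified"` records an ectopic conclusion whose
#' site was not stated.
#'
#' @param location_class One of [location_classes()].
#' @param ectopic_site One of [ectopic_sites()], allowed only when
#'   `location_class = "ectopic"`.
#' @return An object of class `diagnosis`.
#' @export
#' @examples
#' diagnosis("ectopic", "tubal")
#' diagnosis("intrauterine")
diagnosis <- function(location_class = location_classes(), ectopic_site = NULL) {
  location_class <- match.arg(location_class)
  if (!is.null(ectopic_site)) {
    if (location_class != "ectopic")
      stop("ectopic_site may only be given when location_class is 'ectopic'",
           call. = FALSE)
    ectopic_site <- match.arg(ectopic_site, ectopic_sites())
  }
  structure(list(location_class = location_class, ectopic_site = ectopic_site),
            class = "diagnosis")
}

#' @export
print.diagnosis <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.diagnosis <- function(x, ...) {
  if (x$location_class == "ectopic" && !is.null(x$ectopic_site))
    sprintf("ectopic (%s)", x$ectopic_site)
  else
    x$location_class
}
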