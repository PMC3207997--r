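#' Repeat family taxonomy
#'
#' A taxonomy maps repeat class/name strings (as found in RepeatMasker
#' annotations or BED family columns) to a fixed, ordered set of family
#' labels used throughout the quantification. Patterns are regular
#' expressions applied in order; the first match wins and anything unmatched
#' falls into the catch-all family \code{"Other"}.
#'
#' @param families character vector of family labels (unique; must contain
#'   \code{"Other"}, which is appended if missing).
#' @param patterns named character vector: names are regular expressions,
#'   values are family labels; applied in order to the annotation's
#'   class/family string.
#' @return an object of class \code{family_taxonomy}.
#' @examples
#' tax <- family_taxonomy()
#' assign_family(c("SINE/Alu", "LINE/L1", "Unknown/XYZ"), tax)
#' @export
family_taxonomy <- function(families = NULL, patterns = NULL) {
  if (is.null(families)) families <- default_repeat_families()
  if (is.null(patterns)) patterns <- default_family_patterns()
  if (anyDuplicated(families))
    stop("family labels must be unique")
  if (!"Other" %in% families) families <- c(families, "Other")
  bad <- setdiff(unname(patterns), families)
  if (length(bad))
    stop("patterns map to labels absent from 'families': ",
         paste(bad, collapse = ", "))
  structure(list(families = families, patterns = patterns),
            class = "family_taxonomy")
}

#' @export
print.family_taxonomy <- function(x, ...) {
  cat("family_taxonomy with", length(x$families), "families:\n ",
      paste(x$families, collapse = ", "), "\n")
  invisible(x)
}

#' Default family labels
#'
#' The twelve family labels used for family-level quantification: major
#' SINE, LINE, LTR/ERV, DNA-transposon and satellite groups plus a catch-all.
#' @return character vector of labels.
#' @export
default_repeat_families <- function() {
  c("Alu_SINE", "ERV", "TcMar", "hAT", "DNA", "L1", "L2", "LTR",
    "CR1", "Satellite", "MIR", "Other")
}

# Pattern order matters: ERV before the generic LTR rule, TcMar/hAT before
# the generic DNA rule.
default_family_patterns <- function() {
  c("SINE/Alu"    = "Alu_SINE",
    "ERV"         = "ERV",
    "TcMar"       = "TcMar",
    "hAT"         = "hAT",
    "LINE/L1|^L1" = "L1",
    "LINE/L2|^L2" = "L2",
    "CR1"         = "CR1",
    "Satellite"   = "Satellite",
    "MIR"         = "MIR",
    "^DNA"        = "DNA",
    "^LTR"        = "LTR")
}

#' Map repeat class strings to taxonomy families
#'
#' @param x character vector of repeat class/family strings
#'   (e.g. \code{"SINE/Alu"}).
#' @param taxonomy a \code{\link{family_taxonomy}}.
#' @return character vector of family labels; unmatched strings map to
#'   \code{"Other"}. Strings already equal to a family label are kept as is.
#' @export
assign_family <- function(x, taxonomy = family_taxonomy()) {
  stopifnot(inherits(taxonomy, "family_taxonomy"))
  out <- rep("Other", length(x))
  direct <- x %in% taxonomy$families
  out[direct] <- x[direct]
  todo <- !direct
  for (i in seq_along(taxonomy$patterns)) {
    if (!any(todo)) break
    hit <- todo & grepl(names(taxonomy$patterns)[i], x)
    out[hit] <- taxonomy$patterns[[i]]
    todo <- todo & !hit
  }
  out
}
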