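#' The ordered scale of evolutionary age groups
#'
#' An age scale is an ordered set of phylostrata: clade strata from the most
#' ancient (rank 1) to the most recent (rank G). A gene's age is expressed as
#' the rank of the oldest stratum in which a homolog is found. The default
#' scale has 11 groups, from Prokaryota to Mammalia, each with a short label
#' used in compact tables.
#'
#' @param names character vector of group names, ordered from oldest to
#'   youngest. Ranks are assigned 1..G in this order.
#' @param labels optional character vector of short labels, same length as
#'   `names`. Defaults to the names themselves.
#' @return An object of class `age_scale`: a data frame with columns
#'   `rank` (integer), `name`, `label`.
#' @examples
#' sc <- default_age_scale()
#' age_rank(sc, "Pr")        # 1
#' age_rank(sc, "Mammalia")  # 11
#' @export
age_scale <- function(names, labels = names) {
  stopifnot(is.character(names), length(names) >= 1L,
            length(labels) == length(names))
  if (anyDuplicated(names)) stop("age group names must be unique")
  if (anyDuplicated(tolower(labels))) stop("age group labels must be unique")
  out <- data.frame(rank = seq_along(names), name = names, label = labels,
                    stringsAsFactors = FALSE)
  class(out) <- c("age_scale", "data.frame")
  out
}

#' @rdname age_scale
#' @export
default_age_scale <- function() {
  age_scale(
    names = c("Prokaryota", "early Eukaryota", "Viridiplantae", "Unikonta",
              "Opisthokonta", "Metazoa", "Radiata", "Bilateria", "Chordata",
              "Vertebrata", "Mammalia"),
    labels = c("Pr", "E", "V", "U", "O", "M", "R", "B", "Ch", "Vr", "Ma")
  )
}

#' Look up the rank of an age group
#'
#' Accepts full group names or short labels, case-insensitively. Labels are
#' matched as exact tokens, so on the default scale "V" is Viridiplantae and
#' "Vr" is Vertebrata.
#'
#' @param scale an [age_scale()].
#' @param name_or_label character vector of group names or short labels.
#' @return integer vector of ranks.
#' @export
age_rank <- function(scale, name_or_label) {
  stopifnot(inherits(scale, "age_scale"))
  key <- tolower(name_or_label)
  idx <- match(key, tolower(scale$name))
  miss <- is.na(idx)
  idx[miss] <- match(key[miss], tolower(scale$label))
  if (anyNA(idx)) {
    bad <- unique(name_or_label[is.na(idx)])
    stop("unknown age group: ", paste(bad, collapse = ", "),
         "; valid labels: ",
         paste(paste0(scale$name, " (", scale$label, ")"), collapse = ", "))
  }
  scale$rank[idx]
}

#' @export
print.age_scale <- function(x, ...) {
  cat("Age scale with", nrow(x), "groups (1 = most ancient):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
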