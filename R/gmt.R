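#' Gene-set collections
#'
#' A gene-set collection is a tibble with one row per set and columns
#' `set` (unique name), `description`, and `members` (a list-column of
#' deduplicated, nonempty character vectors of gene symbols). A
#' `provenance` attribute labels the source (e.g. "MSigDb-like",
#' "AcIc-curated").
#'
#' @param set Character vector of unique set names.
#' @param members List of character vectors of gene symbols.
#' @param description Character vector of descriptions (recycled if length 1).
#' @param provenance Free-text label for the collection's origin.
#' @return A `geneset_collection` tibble.
#' @export
geneset_collection <- function(set, members, description = "", provenance = "unspecified") {
  if (anyDuplicated(set)) {
    stop("duplicate gene-set names: ", paste(unique(set[duplicated(set)]), collapse = ", "),
         call. = FALSE)
  }
  members <- lapply(members, function(m) {
    m <- unique(trimws(as.character(m)))
    m <- m[nzchar(m)]
    if (!length(m)) stop("gene-set with no members", call. = FALSE)
    m
  })
  if (length(description) == 1L) description <- rep(description, length(set))
  out <- tibble::tibble(set = as.character(set), description = description,
                        members = members)
  attr(out, "provenance") <- provenance
  class(out) <- c("geneset_collection", class(out))
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' name, description, member genes (at least one member).
#' Duplicate member symbols within a line are deduplicated with a warning;
#' duplicate set names or lines with fewer than three fields are hard
#' errors.
#'
#' @param path Path to a GMT file.
#' @param provenance Label recorded on the collection.
#' @return A `geneset_collection` tibble.
#' @export
read_gmt <- function(path, provenance = basename(path)) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  dups <- vapply(members, anyDuplicated, integer(1)) > 0L
  if (any(dups)) {
    warning("duplicate member symbols deduplicated in set(s): ",
            paste(nm[dups], collapse = ", "), call. = FALSE)
  }
  geneset_collection(nm, members, desc, provenance = provenance)
}

#' Write a gene-set collection as GMT
#'
#' `read_gmt(write_gmt(x, path))` is the identity on collections.
#'
#' @param collection A `geneset_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set[i], collection$description[i], collection$members[[i]]),
          collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Look up the members of one set
#' @param collection A `geneset_collection`.
#' @param name Set name.
#' @return Character vector of member symbols.
#' @export
set_members <- function(collection, name) {
  i <- match(name, collection$set)
  if (is.na(i)) stop("no gene-set named '", name, "' in collection", call. = FALSE)
  collection$members[[i]]
}
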