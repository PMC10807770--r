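#' Read a gene set collection from a GMT file
#'
#' Parses the tab-separated GMT format used by MSigDB and most pathway
#' repositories: one set per line, fields are set name, description, then
#' one or more member gene identifiers. Duplicate member identifiers within
#' a line are removed (first occurrence kept); file order of sets is
#' preserved.
#'
#' @param path Path to a GMT file (UTF-8, no quoting).
#' @return A `gene_set_collection`: a named list of character vectors of
#'   gene identifiers, with a `descriptions` attribute (named character
#'   vector, one per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop("GMT file not found: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  set_names <- character(length(lines))
  descriptions <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("Malformed GMT line ", i, ": expected >= 3 tab-separated fields, got ",
           length(fields))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop("Malformed GMT line ", i, ": set '", fields[[1]], "' has no members")
    }
    set_names[[i]] <- fields[[1]]
    descriptions[[i]] <- fields[[2]]
    sets[[i]] <- members
  }
  dup <- duplicated(set_names)
  if (any(dup)) {
    stop("Duplicate gene set name(s) in GMT: ",
         paste(unique(set_names[dup]), collapse = ", "))
  }
  names(sets) <- set_names
  names(descriptions) <- set_names
  new_gene_set_collection(sets, descriptions)
}

#' Write a gene set collection to a GMT file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, f))` reproduces `x`
#' for any canonical collection (unique, nonempty member lists).
#'
#' @param collection A `gene_set_collection` (or plain named list of
#'   character vectors).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  collection <- as_gene_set_collection(collection)
  desc <- attr(collection, "descriptions")
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[[i]], desc[[i]], collection[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

new_gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions,
            class = c("gene_set_collection", "list"))
}

#' Coerce to a gene set collection
#'
#' @param x A named list of character vectors (set name -> members) or an
#'   existing `gene_set_collection`.
#' @return A validated `gene_set_collection`.
#' @export
as_gene_set_collection <- function(x) {
  if (inherits(x, "gene_set_collection")) {
    validate_gene_set_collection(x)
    return(x)
  }
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("A gene set collection must be a named list of character vectors")
  }
  x <- lapply(x, function(m) unique(as.character(m)))
  out <- new_gene_set_collection(x, attr(x, "descriptions"))
  validate_gene_set_collection(out)
  out
}

validate_gene_set_collection <- function(x) {
  if (anyDuplicated(names(x))) {
    stop("Gene set names must be unique")
  }
  sizes <- lengths(x)
  if (any(sizes == 0L)) {
    stop("Empty gene set(s): ", paste(names(x)[sizes == 0L], collapse = ", "))
  }
  dup_within <- vapply(x, anyDuplicated, integer(1)) > 0L
  if (any(dup_within)) {
    stop("Duplicate members within set(s): ",
         paste(names(x)[dup_within], collapse = ", "))
  }
  invisible(x)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene set collection:", length(x), "sets,",
      length(unique(unlist(x, use.names = FALSE))), "distinct genes\n")
  sizes <- lengths(x)
  if (length(x)) {
    cat("  set sizes: min", min(sizes), "/ median", stats::median(sizes),
        "/ max", max(sizes), "\n")
  }
  invisible(x)
}

#' Map a gene set collection onto the gene axis of an expression matrix
#'
#' Resolves each set's members to column indices of `gene_ids` by exact
#' identifier match. Members absent from `gene_ids` are dropped; sets whose
#' surviving size falls below `min_set_size` are dropped and reported via
#' the `dropped_sets` attribute. The per-set surviving size is the set size
#' g entering the distance quadratic form.
#'
#' @param collection A `gene_set_collection`.
#' @param gene_ids Character vector of unique gene identifiers (the column
#'   names of the expression matrix to be scored).
#' @param min_set_size Minimum surviving set size; smaller sets are dropped.
#'   Defaults to 5: below that, a per-set gamma fit and the quadratic form
#'   are statistically fragile.
#' @return A `set_index`: named list of integer index vectors into
#'   `gene_ids`, with attributes `sizes` (named integer vector g per set)
#'   and `dropped_sets` (named integer vector of pre-filter sizes of the
#'   sets removed).
#' @export
build_set_index <- function(collection, gene_ids, min_set_size = 5L) {
  collection <- as_gene_set_collection(collection)
  if (anyDuplicated(gene_ids)) {
    stop("gene_ids must be unique")
  }
  min_set_size <- as.integer(min_set_size)
  idx <- lapply(collection, function(members) {
    i <- match(members, gene_ids)
    as.integer(i[!is.na(i)])
  })
  sizes <- lengths(idx)
  keep <- sizes >= min_set_size
  if (!any(keep)) {
    stop("No gene set retains >= ", min_set_size, " members present in the ",
         "expression matrix; check that gene identifiers use the same ",
         "namespace (e.g. symbols vs Ensembl IDs)")
  }
  out <- idx[keep]
  structure(out,
            sizes = stats::setNames(sizes[keep], names(out)),
            dropped_sets = stats::setNames(sizes[!keep],
                                           names(collection)[!keep]),
            class = c("set_index", "list"))
}

#' @export
print.set_index <- function(x, ...) {
  cat("Set index:", length(x), "sets retained,",
      length(attr(x, "dropped_sets")), "dropped\n")
  invisible(x)
}
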