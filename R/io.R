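#' Read a concept map (or a collection of maps) from file
#'
#' Supported formats:
#' \describe{
#'   \item{\code{edgelist}}{CSV with header \code{source,target,weight}; one
#'     row per directed edge; nodes are implied by the edges (undeclared
#'     nodes are auto-added).}
#'   \item{\code{adjacency}}{labeled square CSV: first column and header row
#'     are concept labels, cell (i, j) is the weight of i -> j, 0 = absent.}
#'   \item{\code{collection}}{JSON with fields \code{universe}, \code{maps}
#'     (each \code{\{"id", "edges": [[source, target, weight], ...]\}}) and
#'     optional \code{identities}; returns a list of \code{concept_map}
#'     (with identities attached as attribute \code{"identities"}).}
#' }
#'
#' @param source path to a file (or a connection).
#' @param format one of \code{"edgelist"}, \code{"adjacency"},
#'   \code{"collection"}.
#' @param id map identifier for single-map formats (defaults to the file
#'   base name).
#' @return a \code{concept_map}, or a list of them for \code{collection}.
#' @export
read_map <- function(source, format = c("edgelist", "adjacency", "collection"),
                     id = NULL) {
  format <- match.arg(format)
  if (is.null(id)) {
    id <- if (is.character(source)) {
      sub("\\.[^.]*$", "", basename(source))
    } else "map"
  }
  switch(format,
    edgelist = {
      df <- utils::read.csv(source, stringsAsFactors = FALSE)
      if (!all(c("source", "target", "weight") %in% names(df))) {
        stop("edge-list CSV must have header source,target,weight")
      }
      concept_map(id, edges = df)
    },
    adjacency = {
      m <- utils::read.csv(source, row.names = 1L, check.names = FALSE)
      m <- as.matrix(m)
      if (nrow(m) != ncol(m) ||
          !identical(canonical_label(rownames(m)), canonical_label(colnames(m)))) {
        stop("adjacency CSV must be square with matching row/column labels")
      }
      storage.mode(m) <- "double"
      nz <- which(m != 0, arr.ind = TRUE)
      edges <- data.frame(source = rownames(m)[nz[, 1L]],
                          target = colnames(m)[nz[, 2L]],
                          weight = m[nz], stringsAsFactors = FALSE)
      concept_map(id, edges = edges, nodes = rownames(m))
    },
    collection = {
      doc <- jsonlite::fromJSON(source, simplifyVector = FALSE)
      maps <- lapply(doc$maps, function(mm) {
        ed <- if (length(mm$edges)) {
          data.frame(
            source = vapply(mm$edges, function(e) as.character(e[[1L]]), ""),
            target = vapply(mm$edges, function(e) as.character(e[[2L]]), ""),
            weight = vapply(mm$edges, function(e) as.numeric(e[[3L]]), 0),
            stringsAsFactors = FALSE)
        } else NULL
        concept_map(mm$id, edges = ed,
                    nodes = unlist(doc$universe, use.names = FALSE))
      })
      if (!is.null(doc$identities)) {
        attr(maps, "identities") <-
          unlist(doc$identities)[vapply(maps, `[[`, "", "id")]
      }
      maps
    })
}

# full-precision decimal text so numeric round trips are exact
.num_text <- function(x) sprintf("%.17g", x)

#' Serialize a concept map
#'
#' The inverse of \code{\link{read_map}} for the single-map formats:
#' \code{read_map(write_map(m, fmt), fmt)} reproduces \code{m} exactly
#' (labels, edges, weights).
#'
#' @param map a \code{concept_map}.
#' @param format \code{"edgelist"} or \code{"adjacency"}.
#' @param path optional output file; when \code{NULL} the serialized text is
#'   returned.
#' @return the serialized text (invisibly when written to \code{path}).
#' @export
write_map <- function(map, format = c("edgelist", "adjacency"), path = NULL) {
  stopifnot(inherits(map, "concept_map"))
  format <- match.arg(format)
  txt <- switch(format,
    edgelist = {
      lines <- c("source,target,weight",
                 if (nrow(map$edges)) {
                   paste(map$edges$source, map$edges$target,
                         .num_text(map$edges$weight), sep = ",")
                 })
      paste0(paste(lines, collapse = "\n"), "\n")
    },
    adjacency = {
      W <- weighted_adjacency(map)
      body <- vapply(seq_len(nrow(W)), function(i) {
        paste(c(rownames(W)[i], .num_text(W[i, ])), collapse = ",")
      }, "")
      paste0(paste(c(paste(c("", colnames(W)), collapse = ","), body),
                   collapse = "\n"), "\n")
    })
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Write a homogenized collection to JSON
#'
#' @param collection an \code{fcm_collection}.
#' @param path optional output file.
#' @return the JSON text (invisibly when written to \code{path}).
#' @export
write_collection <- function(collection, path = NULL) {
  stopifnot(inherits(collection, "fcm_collection"))
  doc <- list(
    universe = collection$universe,
    maps = lapply(collection$maps, function(m) {
      list(id = m$id,
           edges = lapply(seq_len(nrow(m$edges)), function(i) {
             list(m$edges$source[i], m$edges$target[i], m$edges$weight[i])
           }))
    }),
    identities = as.list(collection$identities))
  names(doc$maps) <- NULL
  # 17 significant digits so weights round-trip bit-exactly
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                          pretty = FALSE)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Read a homogenized collection from JSON
#'
#' @param path path to a collection JSON file.
#' @return an \code{fcm_collection}.
#' @export
read_collection <- function(path) {
  maps <- read_map(path, format = "collection")
  identities <- attr(maps, "identities")
  if (is.null(identities)) {
    stop("collection JSON has no identities; supply them separately")
  }
  homogenize_collection(maps, identities)
}

#' Load a synonym table from a raw,canonical CSV (or a data.frame)
#'
#' @param x path to a CSV with header \code{raw,canonical}, or an equivalent
#'   data.frame.
#' @return a \code{synonym_table}.  Errors if the mapping is not
#'   single-valued or contains chains (a canonical term that is itself a raw
#'   key).
#' @export
synonym_table <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  if (!all(c("raw", "canonical") %in% names(df))) {
    stop("synonym table must have columns raw, canonical")
  }
  raw <- as.character(df$raw)
  can <- as.character(df$canonical)
  if (anyDuplicated(canonical_label(raw))) {
    stop("synonym table is not single-valued: duplicate raw term")
  }
  j <- match(canonical_label(can), canonical_label(raw))
  chained <- unique(can[!is.na(j) &
                          canonical_label(can)[j] != canonical_label(raw)[j]])
  if (length(chained)) {
    stop("chained synonym entries (canonical term is also a raw key): ",
         paste(chained, collapse = ", "))
  }
  structure(list(raw = raw, canonical = can), class = "synonym_table")
}

#' Read an identity table (individual id -> group label)
#'
#' @param path CSV whose first two columns are the individual id and the
#'   group label.
#' @return named character vector.
#' @export
read_identities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
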