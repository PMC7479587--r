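#' Construct a bipartite pharmacy-referrer backlink graph
#'
#' A `referral_graph` holds the sparse backlink structure between online
#' pharmacies and the web sites that refer traffic to them: for pharmacy
#' \eqn{i} and referrer \eqn{j}, `l_ij` is the number of backlinks from
#' \eqn{j} to \eqn{i}. Absent pairs mean zero backlinks; stored counts are
#' always at least 1. Pharmacies may be declared without any edges (a
#' pharmacy with no referral data at all is later classified `unknown`).
#'
#' @param edges data frame with columns `pharmacy`, `referrer`, `backlinks`
#'   (character, character, non-negative integer). Duplicate
#'   (pharmacy, referrer) rows are summed; zero-count rows are dropped.
#' @param pharmacies,referrers optional character vectors of additional
#'   identifiers to declare (beyond those appearing in `edges`), e.g.
#'   query pharmacies with no referral data.
#' @return An object of class `referral_graph`: a list with components
#'   `edges` (aggregated, sorted data frame), `pharmacies` and `referrers`
#'   (sorted unique identifier vectors).
#' @examples
#' g <- referral_graph(data.frame(
#'   pharmacy  = c("p1", "p1", "p2"),
#'   referrer  = c("r1", "r3", "r1"),
#'   backlinks = c(5L, 3L, 9L)
#' ))
#' total_backlinks(g, "p1")  # 8
#' @export
referral_graph <- function(edges = NULL, pharmacies = character(),
                           referrers = character()) {
  if (is.null(edges)) {
    edges <- data.frame(pharmacy = character(), referrer = character(),
                        backlinks = integer(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges))
  need <- c("pharmacy", "referrer", "backlinks")
  if (!all(need %in% names(edges))) {
    stop("edges must have columns pharmacy, referrer, backlinks")
  }
  edges <- edges[, need]
  edges$pharmacy <- as.character(edges$pharmacy)
  edges$referrer <- as.character(edges$referrer)
  cnt <- edges$backlinks
  if (length(cnt) && (any(is.na(cnt)) || any(cnt != round(cnt)) || any(cnt < 0))) {
    stop("backlink counts must be non-negative integers")
  }
  edges$backlinks <- as.integer(round(cnt))
  edges <- edges[edges$backlinks > 0L, , drop = FALSE]

  if (nrow(edges)) {
    key <- paste(edges$pharmacy, edges$referrer, sep = "\r")
    if (anyDuplicated(key)) {
      agg <- tapply(edges$backlinks, key, sum)
      parts <- strsplit(names(agg), "\r", fixed = TRUE)
      edges <- data.frame(
        pharmacy  = vapply(parts, `[`, "", 1L),
        referrer  = vapply(parts, `[`, "", 2L),
        backlinks = as.integer(agg),
        stringsAsFactors = FALSE
      )
    }
    edges <- edges[order(edges$pharmacy, edges$referrer), , drop = FALSE]
    rownames(edges) <- NULL
  }

  ph <- sort(unique(c(as.character(pharmacies), edges$pharmacy)))
  rf <- sort(unique(c(as.character(referrers), edges$referrer)))
  if (any(!nzchar(ph)) || any(!nzchar(rf))) {
    stop("identifiers must be non-empty strings")
  }
  structure(list(edges = edges, pharmacies = ph, referrers = rf),
            class = "referral_graph")
}

#' @export
print.referral_graph <- function(x, ...) {
  cat(sprintf("<referral_graph> %d pharmacies, %d referrers, %d edges (total backlinks %d)\n",
              length(x$pharmacies), length(x$referrers), nrow(x$edges),
              sum(x$edges$backlinks)))
  invisible(x)
}

# Split raw delimited lines, auto-detecting tab vs comma from the header.
.detect_delim <- function(header, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.read_table_lines <- function(source) {
  lines <- if (inherits(source, "connection")) readLines(source) else {
    if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
      readLines(source)
    } else {
      unlist(strsplit(paste(source, collapse = "\n"), "\n"))
    }
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a backlink edge table
#'
#' Reads delimited text (comma or tab, auto-detected from the header unless
#' `delim` is given) with columns `pharmacy,referrer,backlinks`. A header row
#' is required; lines starting with `#` are ignored. Duplicate
#' (pharmacy, referrer) rows are summed. Zero counts are accepted and
#' dropped (absence means zero); negative or non-integer counts are errors
#' that name the offending line.
#'
#' @param source file path, connection, or character vector of lines.
#' @param delim optional delimiter override (`","` or `"\t"`).
#' @return A [referral_graph].
#' @export
read_edge_table <- function(source, delim = NULL) {
  tl <- .read_table_lines(source)
  if (!length(tl$lines)) return(referral_graph())
  d <- .detect_delim(tl$lines[1L], delim)
  header <- trimws(tolower(strsplit(tl$lines[1L], d, fixed = TRUE)[[1L]]))
  if (length(header) != 3L || !identical(header, c("pharmacy", "referrer", "backlinks"))) {
    stop(sprintf("line %d: expected header 'pharmacy%sreferrer%sbacklinks'",
                 tl$lineno[1L], d, d))
  }
  body <- tl$lines[-1L]
  nos <- tl$lineno[-1L]
  if (!length(body)) return(referral_graph())
  parts <- strsplit(body, d, fixed = TRUE)
  arity <- lengths(parts)
  if (any(arity != 3L)) {
    bad <- which(arity != 3L)[1L]
    stop(sprintf("line %d: expected 3 fields, found %d", nos[bad], arity[bad]))
  }
  ph <- trimws(vapply(parts, `[`, "", 1L))
  rf <- trimws(vapply(parts, `[`, "", 2L))
  ct_raw <- trimws(vapply(parts, `[`, "", 3L))
  ct <- suppressWarnings(as.numeric(ct_raw))
  bad <- which(is.na(ct) | ct != round(ct) | ct < 0)
  if (length(bad)) {
    stop(sprintf("line %d: backlink count '%s' is not a non-negative integer",
                 nos[bad[1L]], ct_raw[bad[1L]]))
  }
  referral_graph(data.frame(pharmacy = ph, referrer = rf,
                            backlinks = as.integer(ct), stringsAsFactors = FALSE))
}

#' Write a backlink edge table
#'
#' Deterministic inverse of [read_edge_table()]: rows sorted by pharmacy then
#' referrer, so re-reading reproduces the graph bit for bit.
#'
#' @param graph a [referral_graph].
#' @param path output file path or connection.
#' @param delim field delimiter, tab by default.
#' @export
write_edge_table <- function(graph, path, delim = "\t") {
  stopifnot(inherits(graph, "referral_graph"))
  e <- graph$edges
  lines <- c(paste(c("pharmacy", "referrer", "backlinks"), collapse = delim),
             if (nrow(e)) paste(e$pharmacy, e$referrer, e$backlinks, sep = delim))
  writeLines(lines, path)
  invisible(path)
}

.status_aliases <- c(
  legitimate = "legitimate", licit = "legitimate", safe = "legitimate",
  "0" = "legitimate",
  illicit = "illicit", rogue = "illicit", "1" = "illicit"
)

#' Construct a pharmacy label set
#'
#' Ground-truth legitimate/illicit status assignments, partitioning the
#' labeled pharmacies into the safe set (legitimate) and the rogue set
#' (illicit).
#'
#' @param pharmacy character vector of pharmacy identifiers (no duplicates
#'   with conflicting status).
#' @param status character vector of statuses; accepted tokens
#'   (case-insensitive): `legitimate`/`licit`/`safe`/`0` and
#'   `illicit`/`rogue`/`1`.
#' @return An object of class `label_set`: list with `status` (named
#'   character vector, values `"legitimate"` or `"illicit"`, sorted by
#'   pharmacy id), `safe` and `rogue` (the two id vectors).
#' @export
label_set <- function(pharmacy, status) {
  pharmacy <- as.character(pharmacy)
  if (any(!nzchar(pharmacy))) stop("pharmacy identifiers must be non-empty")
  status <- .status_aliases[tolower(trimws(as.character(status)))]
  if (any(is.na(status))) stop("unrecognized status token")
  if (anyDuplicated(pharmacy)) {
    conflict <- tapply(status, pharmacy, function(s) length(unique(s)) > 1L)
    if (any(conflict)) {
      stop(sprintf("conflicting status for pharmacy '%s'",
                   names(conflict)[which(conflict)[1L]]))
    }
    keep <- !duplicated(pharmacy)
    pharmacy <- pharmacy[keep]
    status <- status[keep]
  }
  o <- order(pharmacy)
  st <- stats::setNames(unname(status[o]), pharmacy[o])
  structure(list(status = st,
                 safe = names(st)[st == "legitimate"],
                 rogue = names(st)[st == "illicit"]),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set> %d pharmacies: %d legitimate, %d illicit\n",
              length(x$status), length(x$safe), length(x$rogue)))
  invisible(x)
}

#' Read a pharmacy status label table
#'
#' Delimited text with columns `pharmacy,status`; same dialect rules as
#' [read_edge_table()]. Status tokens are mapped case-insensitively
#' (`legitimate`/`licit`/`safe`/`0`, `illicit`/`rogue`/`1`). Duplicate rows
#' with conflicting status are an error.
#'
#' @inheritParams read_edge_table
#' @return A [label_set].
#' @export
read_labels <- function(source, delim = NULL) {
  tl <- .read_table_lines(source)
  if (!length(tl$lines)) return(label_set(character(), character()))
  d <- .detect_delim(tl$lines[1L], delim)
  header <- trimws(tolower(strsplit(tl$lines[1L], d, fixed = TRUE)[[1L]]))
  if (length(header) != 2L || !identical(header, c("pharmacy", "status"))) {
    stop(sprintf("line %d: expected header 'pharmacy%sstatus'", tl$lineno[1L], d))
  }
  body <- tl$lines[-1L]
  nos <- tl$lineno[-1L]
  if (!length(body)) return(label_set(character(), character()))
  parts <- strsplit(body, d, fixed = TRUE)
  arity <- lengths(parts)
  if (any(arity != 2L)) {
    bad <- which(arity != 2L)[1L]
    stop(sprintf("line %d: expected 2 fields, found %d", nos[bad], arity[bad]))
  }
  tok <- trimws(vapply(parts, `[`, "", 2L))
  unknown <- which(is.na(.status_aliases[tolower(tok)]))
  if (length(unknown)) {
    stop(sprintf("line %d: unrecognized status token '%s'",
                 nos[unknown[1L]], tok[unknown[1L]]))
  }
  label_set(trimws(vapply(parts, `[`, "", 1L)), tok)
}

#' Write a pharmacy status label table
#'
#' @param labels a [label_set].
#' @inheritParams write_edge_table
#' @export
write_labels <- function(labels, path, delim = "\t") {
  stopifnot(inherits(labels, "label_set"))
  lines <- c(paste(c("pharmacy", "status"), collapse = delim),
             if (length(labels$status))
               paste(names(labels$status), unname(labels$status), sep = delim))
  writeLines(lines, path)
  invisible(path)
}

#' Backlink count vector of a pharmacy on a referrer axis
#'
#' Projects one pharmacy's row of the backlink matrix onto an ordered list
#' of referrers: position \eqn{k} holds \eqn{l_{i,\mathrm{axis}[k]}}, zero
#' where no edge exists. A pharmacy absent from the graph yields the
#' all-zero vector.
#'
#' @param graph a [referral_graph].
#' @param pharmacy a single pharmacy identifier.
#' @param axis ordered character vector of referrer identifiers (need not be
#'   a subset of the graph's referrers).
#' @return Named integer vector along `axis`.
#' @export
backlink_vector <- function(graph, pharmacy, axis) {
  stopifnot(inherits(graph, "referral_graph"), length(pharmacy) == 1L)
  v <- stats::setNames(integer(length(axis)), axis)
  e <- graph$edges
  e <- e[e$pharmacy == pharmacy & e$referrer %in% axis, , drop = FALSE]
  if (nrow(e)) v[e$referrer] <- e$backlinks
  v
}

#' Total backlinks to a pharmacy
#'
#' \eqn{L_i = \sum_j l_{ij}}: the total number of backlinks pointing at a
#' pharmacy across all referrers; 0 for a pharmacy with no edges.
#'
#' @inheritParams backlink_vector
#' @return Non-negative integer.
#' @export
total_backlinks <- function(graph, pharmacy) {
  stopifnot(inherits(graph, "referral_graph"), length(pharmacy) == 1L)
  e <- graph$edges
  sum(e$backlinks[e$pharmacy == pharmacy])
}

# Dense backlink matrix (pharmacies x axis) for vectorized scoring.
# Counts are small integers, so doubles hold them exactly.
.backlink_matrix <- function(graph, pharmacies, axis) {
  m <- matrix(0, nrow = length(pharmacies), ncol = length(axis),
              dimnames = list(pharmacies, axis))
  e <- graph$edges
  e <- e[e$pharmacy %in% pharmacies & e$referrer %in% axis, , drop = FALSE]
  if (nrow(e)) {
    m[cbind(match(e$pharmacy, pharmacies), match(e$referrer, axis))] <- e$backlinks
  }
  m
}

# Pharmacies that have at least one edge (the rest are 'unknown' at
# classification time).
.pharmacies_with_edges <- function(graph) unique(graph$edges$pharmacy)

# Restrict a label set to a subset of pharmacies.
.subset_labels <- function(labels, ids) {
  st <- labels$status[names(labels$status) %in% ids]
  label_set(names(st), unname(st))
}
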