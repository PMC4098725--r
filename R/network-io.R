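# readers and writers for the on-disk formats:
#   * PPI edge lists       TSV  protein_a TAB protein_b [TAB weight]
#   * ortholog groups      OrthoMCL dialect  "group_id: sp|prot sp|prot ..."
#   * complex catalogs     membership_rows (complex_id TAB protein [TAB count])
#                          or one_per_line (complex_id TAB "m1 m2 m3")
#   * interolog networks   TSV  "p|q" TAB "r|s" TAB weight TAB provenance
# '#' starts a comment line everywhere; header rows are only skipped when
# asked for explicitly (no auto-detection).

.read_lines <- function(path, header = FALSE) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  ln <- which(keep)
  lines <- lines[keep]
  if (header && length(lines)) {
    lines <- lines[-1L]
    ln <- ln[-1L]
  }
  list(text = lines, lineno = ln)
}

#' Read a PPI network from a tab-separated edge list
#'
#' Each non-comment line holds `protein_a TAB protein_b` and, when
#' `weighted = TRUE`, a third column with a reliability weight in `(0, 1]`.
#' Self-loops are dropped and duplicate or reversed-duplicate edges collapsed
#' (keeping the maximum weight); the number of dropped lines is reported via
#' [message()].
#'
#' @param path input file path.
#' @param species species label for the returned network.
#' @param weighted parse a third weight column (`FALSE`: all weights 1).
#' @param header skip one leading (non-comment) header line.
#' @return a [PPINetwork-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("p1\tp2", "p2\tp1", "p3\tp3"), f)
#' readPPIEdgelist(f, "yeast")
#' @export
readPPIEdgelist <- function(path, species, weighted = FALSE, header = FALSE) {
  src <- .read_lines(path, header)
  if (!length(src$text)) return(ppiNetwork(species))
  parts <- strsplit(src$text, "\t", fixed = TRUE)
  need <- if (weighted) 3L else 2L
  bad <- which(lengths(parts) < need)
  if (length(bad))
    .stopf("malformed edge line %d in %s: expected >= %d tab-separated fields",
           src$lineno[bad[1L]], path, need)
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
    if (anyNA(w))
      .stopf("malformed weight on line %d in %s",
             src$lineno[which(is.na(w))[1L]], path)
    if (any(w <= 0 | w > 1))
      .stopf("weight outside (0,1] on line %d in %s",
             src$lineno[which(w <= 0 | w > 1)[1L]], path)
  } else {
    w <- rep(1, length(a))
  }
  net <- ppiNetwork(species, data.frame(a = a, b = b, weight = w,
                                        stringsAsFactors = FALSE))
  dropped <- length(a) - numEdges(net)
  if (dropped > 0L)
    message(sprintf("readPPIEdgelist: dropped %d self-loop/duplicate line(s) from %s",
                    dropped, path))
  net
}

#' Write a PPI network as a tab-separated edge list
#'
#' Inverse of [readPPIEdgelist()]; isolated nodes are preserved as comment
#' lines `# node <id>` so that round-trips are exact.
#'
#' @param x a [PPINetwork-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writePPIEdgelist <- function(x, path) {
  stopifnot(is(x, "PPINetwork"))
  e <- x@edges
  iso <- setdiff(x@nodes, c(e$a, e$b))
  lines <- c(sprintf("# node %s", iso),
             sprintf("%s\t%s\t%.17g", e$a, e$b, e$weight))
  .write_lines(lines, path)
}

.write_lines <- function(lines, path) {
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    .stopf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# isolated nodes written by writePPIEdgelist are recovered here
#' Read back a PPI edge list including isolated-node annotations
#' @inheritParams readPPIEdgelist
#' @return a [PPINetwork-class].
#' @keywords internal
.readPPIFull <- function(path, species) {
  lines <- readLines(path, warn = FALSE)
  iso <- sub("^# node ", "", lines[grepl("^# node ", lines)])
  net <- readPPIEdgelist(path, species, weighted = TRUE)
  ppiNetwork(species, net@edges, nodes = c(net@nodes, iso))
}

#' Read an OrthoMCL-style ortholog-group file
#'
#' One group per line: `group_id: species|protein species|protein ...`.
#' Species tags must be one of `speciesA`/`speciesB`. Groups whose members
#' all come from one species are retained as paralog groups (they contribute
#' no cross-species ortholog pairs).
#'
#' @param path input file path.
#' @param speciesA,speciesB the species tags expected in the file; `speciesA`
#'   becomes side `a` of the map.
#' @return an [OrthologMap-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("G1: y|p1 h|q1 h|q2", "G2: y|p2 y|p3"), f)
#' readOrthologGroups(f, "y", "h")
#' @export
readOrthologGroups <- function(path, speciesA, speciesB) {
  src <- .read_lines(path)
  groups <- list()
  for (i in seq_along(src$text)) {
    line <- src$text[i]
    m <- regmatches(line, regexec("^\\s*([^:\\s]+):\\s*(.*)$", line))[[1L]]
    if (length(m) != 3L)
      .stopf("malformed group line %d in %s", src$lineno[i], path)
    gid <- m[2L]
    if (gid %in% names(groups))
      .stopf("duplicate group id '%s' on line %d in %s", gid, src$lineno[i], path)
    toks <- strsplit(trimws(m[3L]), "\\s+")[[1L]]
    toks <- toks[toks != ""]
    sp <- sub("\\|.*$", "", toks)
    prot <- sub("^[^|]*\\|", "", toks)
    unknown <- !(sp %in% c(speciesA, speciesB))
    if (any(unknown))
      .stopf("unknown species tag '%s' on line %d in %s",
             sp[unknown][1L], src$lineno[i], path)
    groups[[gid]] <- list(a = prot[sp == speciesA], b = prot[sp == speciesB])
  }
  orthologMap(speciesA, speciesB, groups)
}

#' Write an ortholog map in the OrthoMCL group-file dialect
#'
#' @param x an [OrthologMap-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeOrthologGroups <- function(x, path) {
  stopifnot(is(x, "OrthologMap"))
  lines <- vapply(names(x@groups), function(gid) {
    g <- x@groups[[gid]]
    members <- c(if (length(g$a)) paste(x@speciesA, g$a, sep = "|"),
                 if (length(g$b)) paste(x@speciesB, g$b, sep = "|"))
    paste0(gid, ": ", paste(members, collapse = " "))
  }, character(1))
  .write_lines(unname(lines), path)
}

#' Read a complex catalog
#'
#' Two TSV dialects are supported. `membership_rows`: one membership per row,
#' columns `complex_id TAB protein [TAB count]`; duplicate (complex, protein)
#' rows collapse to multiplicity 1 unless the optional count column is
#' present. `one_per_line`: `complex_id TAB member member member ...`
#' (space-separated members, which may repeat for multiplicity).
#'
#' @param path input file path.
#' @param species species label.
#' @param dialect `"membership_rows"` or `"one_per_line"`.
#' @param header skip one leading header line.
#' @return a [ComplexCatalog-class].
#' @export
readComplexCatalog <- function(path, species,
                               dialect = c("membership_rows", "one_per_line"),
                               header = FALSE) {
  dialect <- match.arg(dialect)
  src <- .read_lines(path, header)
  cx <- list()
  if (dialect == "membership_rows") {
    parts <- strsplit(src$text, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad))
      .stopf("malformed membership row on line %d in %s", src$lineno[bad[1L]], path)
    id <- vapply(parts, `[[`, character(1), 1L)
    prot <- vapply(parts, `[[`, character(1), 2L)
    cnt <- vapply(parts, function(p) {
      if (length(p) >= 3L) {
        n <- suppressWarnings(as.integer(p[[3L]]))
        if (is.na(n) || n < 1L) NA_integer_ else n
      } else 1L
    }, integer(1))
    if (anyNA(cnt)) .stopf("malformed repeat count in %s", path)
    has_count <- vapply(parts, function(p) length(p) >= 3L, logical(1))
    for (cid in unique(id)) {
      rows <- id == cid
      if (any(has_count[rows])) {
        members <- rep(prot[rows], cnt[rows])
      } else {
        members <- unique(prot[rows])
      }
      cx[[cid]] <- members
    }
  } else {
    parts <- strsplit(src$text, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad))
      .stopf("malformed one_per_line row on line %d in %s", src$lineno[bad[1L]], path)
    for (i in seq_along(parts)) {
      cid <- parts[[i]][[1L]]
      if (cid %in% names(cx))
        .stopf("duplicate complex id '%s' on line %d in %s",
               cid, src$lineno[i], path)
      members <- strsplit(parts[[i]][[2L]], "\\s+")[[1L]]
      members <- members[members != ""]
      cx[[cid]] <- members
    }
  }
  if (any(lengths(cx) == 0L))
    .stopf("empty complex after parsing in %s", path)
  complexCatalog(species, cx)
}

#' Write a complex catalog (or cluster set) in the one_per_line dialect
#'
#' Each line holds `complex_id TAB member member ...`; members repeat to
#' encode multiplicity, so `readComplexCatalog(..., "one_per_line")`
#' round-trips exactly.
#'
#' @param x a [ComplexCatalog-class] or [ClusterSet-class] (clusters are
#'   written as `cluster_001`, `cluster_002`, ...).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeClusters <- function(x, path) {
  if (is(x, "ClusterSet")) x <- asComplexCatalog(x)
  stopifnot(is(x, "ComplexCatalog"))
  lines <- vapply(names(x@complexes), function(cid) {
    paste0(cid, "\t", paste(x@complexes[[cid]], collapse = " "))
  }, character(1))
  .write_lines(unname(lines), path)
}

#' Coerce a ClusterSet to a ComplexCatalog
#'
#' @param x a [ClusterSet-class].
#' @param species species label for the catalog (default: the cluster set's
#'   graph label).
#' @return a [ComplexCatalog-class] with ids `cluster_001`, ...
#' @export
asComplexCatalog <- function(x, species = x@graphLabel) {
  stopifnot(is(x, "ClusterSet"))
  cx <- x@clusters
  if (length(cx))
    names(cx) <- sprintf("cluster_%03d", seq_along(cx))
  complexCatalog(species, cx)
}

#' Write an interolog network
#'
#' TSV with one edge per line: the two node ids (`protein_a|protein_b`
#' pairs), the edge weight and the provenance tag; isolated nodes are kept as
#' `# node` comments.
#'
#' @param x an [InterologNetwork-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeInterologNetwork <- function(x, path) {
  stopifnot(is(x, "InterologNetwork"))
  e <- x@edges
  iso <- setdiff(x@nodes$id, c(e$from, e$to))
  lines <- c(sprintf("# species\t%s\t%s", x@speciesA, x@speciesB),
             sprintf("# node %s", iso),
             sprintf("%s\t%s\t%.17g\t%s", e$from, e$to, e$weight, e$provenance))
  .write_lines(lines, path)
}

#' Read an interolog network written by [writeInterologNetwork()]
#'
#' @param path input file path.
#' @return an [InterologNetwork-class].
#' @export
readInterologNetwork <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  sp <- lines[grepl("^# species\t", lines)]
  if (!length(sp)) .stopf("missing '# species' line in %s", path)
  spp <- strsplit(sp[1L], "\t", fixed = TRUE)[[1L]]
  iso <- sub("^# node ", "", lines[grepl("^# node ", lines)])
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) < 4L)) .stopf("malformed interolog edge line in %s", path)
    edges <- data.frame(from = vapply(parts, `[[`, character(1), 1L),
                        to = vapply(parts, `[[`, character(1), 2L),
                        weight = as.numeric(vapply(parts, `[[`, character(1), 3L)),
                        provenance = vapply(parts, `[[`, character(1), 4L),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), provenance = character(0),
                        stringsAsFactors = FALSE)
  }
  ids <- sort(unique(c(iso, edges$from, edges$to)), method = "radix")
  coords <- strsplit(ids, "|", fixed = TRUE)
  nodes <- data.frame(p = vapply(coords, `[[`, character(1), 1L),
                      q = vapply(coords, function(x) paste(x[-1L], collapse = "|"),
                                 character(1)),
                      id = ids, stringsAsFactors = FALSE)
  .interologNetwork(spp[2L], spp[3L], nodes, edges)
}
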