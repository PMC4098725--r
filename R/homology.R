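# ortholog-group algebra: the many-to-many correspondence theta and
# per-complex group-multiplicity profiles

#' Cross-species ortholog pairs (the correspondence theta)
#'
#' Enumerates every cross-species member product of every group of the map:
#' `(p, q)` is a theta pair when some group contains `p` on side a and `q` on
#' side b. Paralog-only groups contribute nothing. The result is a
#' deterministic, duplicate-free table, optionally intersected with
#' restriction sets on either side.
#'
#' @param map an [OrthologMap-class].
#' @param restrictA,restrictB optional protein sets; when given, only pairs
#'   whose respective coordinate lies in the set are returned.
#' @return data.frame with columns `a`, `b`, sorted lexicographically.
#' @examples
#' m <- orthologMap("y", "h", list(G1 = list(a = "p1", b = c("q1", "q2"))))
#' thetaPairs(m)
#' @export
thetaPairs <- function(map, restrictA = NULL, restrictB = NULL) {
  stopifnot(is(map, "OrthologMap"))
  pieces <- lapply(map@groups, function(g) {
    a <- g$a; b <- g$b
    if (!is.null(restrictA)) a <- a[a %in% restrictA]
    if (!is.null(restrictB)) b <- b[b %in% restrictB]
    if (!length(a) || !length(b)) return(NULL)
    expand.grid(a = a, b = b, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    return(data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE))
  out <- out[!duplicated(paste(out$a, out$b, sep = "\r")), , drop = FALSE]
  out <- out[order(out$a, out$b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group-multiplicity profile of a complex
#'
#' For each ortholog group, counts how many members of the complex are
#' assigned to it on the chosen species side -- the group's multiplicity in
#' the complex, i.e. the number of paralogs of that group the complex
#' contains. A protein belonging to k groups contributes 1 to each of the k
#' multiplicities; members assigned to no group are collected in the
#' `ungrouped` multiset.
#'
#' @param members character multiset of complex members (repeats allowed).
#' @param side `"a"` or `"b"`: which species' group membership to consult.
#' @param map an [OrthologMap-class].
#' @param complexId identifier stored in the profile.
#' @return a [GroupProfile-class].
#' @examples
#' m <- orthologMap("y", "h", list(G1 = list(a = c("p1", "p2"), b = "q1")))
#' groupProfile(c("p1", "p2", "p3"), "a", m)
#' @export
groupProfile <- function(members, side = c("a", "b"), map, complexId = "") {
  side <- match.arg(side)
  stopifnot(is(map, "OrthologMap"))
  members <- as.character(members)
  idx <- .membership_index(map, side)
  mult <- integer(0)
  ungrouped <- character(0)
  for (p in members) {
    gs <- idx[[p]]
    if (is.null(gs)) {
      ungrouped <- c(ungrouped, p)
    } else {
      for (g in gs) mult[g] <- (if (is.na(mult[g])) 0L else mult[g]) + 1L
    }
  }
  mult <- mult[!is.na(mult)]
  if (length(mult)) mult <- mult[order(names(mult), method = "radix")]
  new("GroupProfile", complexId = as.character(complexId),
      multiplicities = mult, ungrouped = sort(ungrouped, method = "radix"))
}

# protein -> character vector of group ids, for one side of the map
.membership_index <- function(map, side) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (gid in names(map@groups)) {
    for (p in map@groups[[gid]][[side]]) {
      idx[[p]] <- c(idx[[p]], gid)
    }
  }
  as.list(idx)
}

#' Union-merge two ortholog maps
#'
#' Combines the groups of two maps over the same species pair. Groups are
#' kept as-is; a clashing group id present in both maps keeps the union of
#' its members. This is a deliberately simple interpretation for combining
#' orthology resources that were built independently (e.g. a domain-aware
#' and a sequence-similarity-based resource).
#'
#' @param x,y [OrthologMap-class] objects with identical species labels.
#' @return an [OrthologMap-class].
#' @export
mergeOrthologMaps <- function(x, y) {
  stopifnot(is(x, "OrthologMap"), is(y, "OrthologMap"))
  if (!identical(speciesLabels(x), speciesLabels(y)))
    .stopf("cannot merge maps with different species labels")
  groups <- x@groups
  for (gid in names(y@groups)) {
    if (gid %in% names(groups)) {
      groups[[gid]] <- list(a = union(groups[[gid]]$a, y@groups[[gid]]$a),
                            b = union(groups[[gid]]$b, y@groups[[gid]]$b))
    } else {
      groups[[gid]] <- y@groups[[gid]]
    }
  }
  orthologMap(x@speciesA, x@speciesB, groups)
}
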