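# internal helpers shared across modules

# canonical undirected edge table: endpoints ordered lexicographically within
# each row, self-loops dropped, duplicates collapsed keeping the max weight,
# rows sorted for deterministic output
.canonical_edges <- function(a, b, weight = NULL) {
  a <- as.character(a)
  b <- as.character(b)
  if (is.null(weight)) weight <- rep(1, length(a))
  weight <- as.numeric(weight)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; weight <- weight[keep]
  swap <- a > b
  if (any(swap)) {
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    if (anyDuplicated(key)) {
      w <- tapply(weight, key, max)
      first <- !duplicated(key)
      ord_key <- key[first]
      a <- a[first]; b <- b[first]
      weight <- as.numeric(w[ord_key])
    }
    ord <- order(a, b, method = "radix")
    a <- a[ord]; b <- b[ord]; weight <- weight[ord]
  }
  data.frame(a = a, b = b, weight = weight, stringsAsFactors = FALSE)
}

.edge_key <- function(a, b) {
  swap <- a > b
  if (any(swap)) {
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  paste(a, b, sep = "\r")
}

.empty_edges <- function() {
  data.frame(a = character(0), b = character(0), weight = numeric(0),
             stringsAsFactors = FALSE)
}

# run code with a private RNG stream, restoring the caller's state afterwards
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
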