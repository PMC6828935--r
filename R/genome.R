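## Genomes as multi-chromosomal signed permutations ---------------------------

#' Construct a genome
#'
#' A genome is a list of linear chromosomes, each an ordered vector of
#' signed syntenic-block labels.  A chromosome `X` and its reverse
#' complement `-X` (reversed order, flipped signs) denote the same
#' molecule.  Absolute labels must be unique across the whole genome:
#' every block occurs exactly once.
#'
#' @param chromosomes list of non-empty integer vectors (or a single
#'   vector for a uni-chromosomal genome); labels are non-zero and their
#'   absolute values unique genome-wide.
#' @param name genome name (used to bind leaves of a phylogeny).
#' @return an object of class `"genome"`.
#' @examples
#' g <- genome(list(c(1, 2, 3, 4)), name = "G1")
#' @export
genome <- function(chromosomes, name = "") {
  if (is.numeric(chromosomes)) chromosomes <- list(chromosomes)
  chromosomes <- lapply(unname(chromosomes), function(v) {
    v <- as.integer(v)
    if (length(v) == 0L) stop("empty chromosome")
    if (any(v == 0L)) stop("0 is reserved for telomere caps")
    if (any(abs(v) > .ADJ_MAX_LABEL))
      stop("block labels above ", .ADJ_MAX_LABEL, " are not supported")
    v
  })
  labs <- abs(unlist(chromosomes))
  if (anyDuplicated(labs))
    stop("duplicated block label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  structure(list(name = name, chromosomes = chromosomes), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("Genome '%s': %d chromosome(s), %d blocks\n", x$name,
              length(x$chromosomes), sum(lengths(x$chromosomes))))
  for (i in seq_along(x$chromosomes))
    cat(" ", paste(x$chromosomes[[i]], collapse = " "), "$\n")
  invisible(x)
}

## Orientation-normal form of one chromosome: whichever of X / -X is
## lexicographically smaller by the (|label|, sign) sequence (negative sign
## sorts after positive).  Adjacency sets are unaffected by this choice.
.normalize_chromosome <- function(v) {
  w <- -rev(v)
  key <- function(u) rbind(abs(u), u < 0L)
  kv <- key(v); kw <- key(w)
  for (i in seq_along(v)) {
    if (kv[1L, i] != kw[1L, i]) return(if (kv[1L, i] < kw[1L, i]) v else w)
    if (kv[2L, i] != kw[2L, i]) return(if (kv[2L, i] < kw[2L, i]) v else w)
  }
  v # palindromic under reverse-complement; either form
}

#' Normalize a genome for comparison
#'
#' Puts every chromosome into its orientation-normal form (the smaller of
#' `X`/`-X`) and sorts chromosomes by their first absolute label, so that
#' two genomes describing the same set of molecules compare `identical()`.
#'
#' @param g a `genome`.
#' @return a `genome` in normal form.
#' @export
normalize_genome <- function(g) {
  chrs <- lapply(g$chromosomes, .normalize_chromosome)
  ord <- order(vapply(chrs, function(v) abs(v[1L]), integer(1L)))
  genome(chrs[ord], name = g$name)
}

#' Test two genomes for equality up to chromosome orientation and order
#'
#' @param g1,g2 `genome` objects.
#' @return logical.
#' @export
genomes_equal <- function(g1, g2) {
  identical(normalize_genome(g1)$chromosomes, normalize_genome(g2)$chromosomes)
}

#' Adjacency set of a genome
#'
#' Every pair of consecutive blocks on a chromosome contributes one
#' adjacency.  With `capped = TRUE` each chromosome additionally
#' contributes the telomere-capped adjacencies `a(0, c1)` and `a(cn, 0)`
#' (the RGRPT convention).
#'
#' @param g a `genome`.
#' @param capped include telomere caps?
#' @return sorted integer vector of canonical adjacency codes.
#' @examples
#' g <- genome(list(1:4))
#' format_adjacency(adjacencies(g))            # a(1,2) a(2,3) a(3,4)
#' length(adjacencies(g, capped = TRUE))       # adds a(0,1) and a(4,0)
#' @export
adjacencies <- function(g, capped = FALSE) {
  codes <- integer(0)
  for (v in g$chromosomes) {
    n <- length(v)
    if (n > 1L) codes <- c(codes, canonical_adjacency(v[-n], v[-1L]))
    if (capped)
      codes <- c(codes, canonical_adjacency(0L, v[1L]),
                 canonical_adjacency(v[n], 0L))
  }
  sort(unique(codes))
}

#' Effective adjacencies of a set of genomes
#'
#' An adjacency is effective with respect to a set of genomes when it is
#' present in at least one genome but not in all of them -- the raw signal
#' of rearrangement.
#'
#' @param genomes list of `genome` objects (at least two).
#' @param capped include telomere caps?
#' @return sorted integer vector of canonical adjacency codes.
#' @examples
#' g1 <- genome(list(1:4)); g2 <- genome(list(c(1, -3, -2, 4)))
#' format_adjacency(effective_adjacencies(list(g1, g2)))
#' @export
effective_adjacencies <- function(genomes, capped = FALSE) {
  if (length(genomes) < 2L)
    stop("effective adjacencies need at least two genomes")
  sets <- lapply(genomes, adjacencies, capped = capped)
  sort(setdiff(Reduce(union, sets), Reduce(intersect, sets)))
}

## Event records --------------------------------------------------------------

.new_event <- function(type, params, destroyed, created, edge_id = NA_integer_) {
  keep_d <- setdiff(destroyed, created)
  keep_c <- setdiff(created, destroyed)
  structure(list(type = type, edge_id = edge_id, params = params,
                 destroyed = sort(unique(keep_d)),
                 created = sort(unique(keep_c))),
            class = "rearrangement_event")
}

#' @export
print.rearrangement_event <- function(x, ...) {
  cat(sprintf("%s  destroyed: {%s}  created: {%s}\n", x$type,
              paste(format_adjacency(x$destroyed), collapse = " "),
              paste(format_adjacency(x$created), collapse = " ")))
  invisible(x)
}

.cap_left <- function(v, i) if (i > 1L) v[i - 1L] else 0L
.cap_right <- function(v, j) if (j < length(v)) v[j + 1L] else 0L

## Rearrangement operators ----------------------------------------------------
##
## Each operator returns list(genome =, event =).  Destroyed/created
## adjacency sets are recorded in telomere-capped terms (caps drop out of
## the record whenever an event touches no chromosome end), so that
## adjacencies(g', capped = TRUE) == (adjacencies(g, TRUE) \ destroyed) U created.

#' Apply a reversal
#'
#' Reverses the segment `i..j` (1-based, inclusive) of one chromosome and
#' flips the signs of its blocks.
#'
#' @param g a `genome`.
#' @param chrom chromosome index.
#' @param i,j segment bounds, `1 <= i <= j <= length`.
#' @return `list(genome =, event =)`.
#' @examples
#' apply_reversal(genome(list(1:4)), 1, 2, 3)$genome  # 1 -3 -2 4
#' @export
apply_reversal <- function(g, chrom, i, j) {
  v <- g$chromosomes[[chrom]]
  n <- length(v)
  if (i < 1L || j > n || i > j) stop("reversal indices out of range")
  left <- .cap_left(v, i); right <- .cap_right(v, j)
  destroyed <- c(canonical_adjacency(left, v[i]), canonical_adjacency(v[j], right))
  created <- c(canonical_adjacency(left, -v[j]), canonical_adjacency(-v[i], right))
  v[i:j] <- -rev(v[i:j])
  g$chromosomes[[chrom]] <- v
  list(genome = g,
       event = .new_event("reversal", list(chrom = chrom, i = i, j = j),
                          destroyed, created))
}

#' Apply a translocation
#'
#' Exchanges end segments between two chromosomes.  With split points
#' `i` and `j`, chromosome `X` is cut into `X1 = x[1..i-1]`, `X2 = x[i..]`
#' and `Y` into `Y1 = y[1..j-1]`, `Y2 = y[j..]`; all four segments must be
#' non-empty (an exchange that empties a chromosome would be a fusion or
#' fission, which are separate operators).  Mode `"prefix-prefix"` forms
#' `Y1 X2` and `X1 Y2`; mode `"prefix-suffix"` forms `-Y2 X2` and `X1 -Y1`.
#'
#' @param g a `genome`.
#' @param c1,c2 distinct chromosome indices.
#' @param i,j split points, `2 <= i <= length(X)`, `2 <= j <= length(Y)`.
#' @param mode `"prefix-prefix"` or `"prefix-suffix"`.
#' @return `list(genome =, event =)`.
#' @export
apply_translocation <- function(g, c1, c2, i, j,
                                mode = c("prefix-prefix", "prefix-suffix")) {
  mode <- match.arg(mode)
  if (c1 == c2) stop("translocation needs two distinct chromosomes")
  v <- g$chromosomes[[c1]]; w <- g$chromosomes[[c2]]
  if (i < 2L || i > length(v) || j < 2L || j > length(w))
    stop("translocation split would produce an empty chromosome")
  destroyed <- c(canonical_adjacency(v[i - 1L], v[i]),
                 canonical_adjacency(w[j - 1L], w[j]))
  x1 <- v[seq_len(i - 1L)]; x2 <- v[i:length(v)]
  y1 <- w[seq_len(j - 1L)]; y2 <- w[j:length(w)]
  if (mode == "prefix-prefix") {
    newx <- c(y1, x2); newy <- c(x1, y2)
    created <- c(canonical_adjacency(w[j - 1L], v[i]),
                 canonical_adjacency(v[i - 1L], w[j]))
  } else {
    newx <- c(-rev(y2), x2); newy <- c(x1, -rev(y1))
    created <- c(canonical_adjacency(-w[j], v[i]),
                 canonical_adjacency(v[i - 1L], -w[j - 1L]))
  }
  g$chromosomes[[c1]] <- newx
  g$chromosomes[[c2]] <- newy
  list(genome = g,
       event = .new_event("translocation",
                          list(c1 = c1, c2 = c2, i = i, j = j, mode = mode),
                          destroyed, created))
}

#' Apply a transposition
#'
#' Excises the fragment `i..j` of the source chromosome and reinserts it,
#' orientation preserved, immediately after position `k` of the
#' destination chromosome (`k = 0` inserts at the head).  When source and
#' destination coincide, `k` must lie outside `[i-1, j]` (positions inside
#' the fragment are meaningless and `k = i-1` is the identity).  The
#' fragment may not be a whole chromosome (that would change the
#' chromosome count, i.e. be a fusion/fission).
#'
#' @param g a `genome`.
#' @param chrom source chromosome index.
#' @param i,j fragment bounds, `1 <= i <= j`.
#' @param dest destination chromosome index (defaults to `chrom`).
#' @param k insert after this position of `dest` (0 = head).
#' @return `list(genome =, event =)`.
#' @examples
#' apply_transposition(genome(list(1:5)), 1, 2, 3, k = 5)$genome  # 1 4 5 2 3
#' @export
apply_transposition <- function(g, chrom, i, j, dest = chrom, k) {
  v <- g$chromosomes[[chrom]]
  n <- length(v)
  if (i < 1L || j > n || i > j) stop("transposition fragment out of range")
  if (i == 1L && j == n) stop("fragment may not be a whole chromosome")
  w <- g$chromosomes[[dest]]
  if (k < 0L || k > length(w)) stop("transposition target out of range")
  if (dest == chrom && k >= i - 1L && k <= j)
    stop("transposition target inside (or identical to) the moved fragment")
  frag <- v[i:j]
  dl <- .cap_left(v, i); dr <- .cap_right(v, j)
  tk <- if (k > 0L) w[k] else 0L
  tk1 <- if (k < length(w)) w[k + 1L] else 0L
  destroyed <- c(canonical_adjacency(dl, v[i]), canonical_adjacency(v[j], dr),
                 canonical_adjacency(tk, tk1))
  created <- c(canonical_adjacency(dl, dr),
               canonical_adjacency(tk, frag[1L]),
               canonical_adjacency(frag[length(frag)], tk1))
  if (dest == chrom) {
    rest <- v[-(i:j)]
    k2 <- if (k < i) k else k - (j - i + 1L)
    g$chromosomes[[chrom]] <- append(rest, frag, after = k2)
  } else {
    g$chromosomes[[chrom]] <- v[-(i:j)]
    g$chromosomes[[dest]] <- append(w, frag, after = k)
  }
  list(genome = g,
       event = .new_event("transposition",
                          list(chrom = chrom, i = i, j = j, dest = dest, k = k),
                          destroyed, created))
}

#' Apply a fusion
#'
#' Joins two chromosomes into one: `X Y` (`orient = "same"`) or
#' `X -Y` (`orient = "flip"`, the second chromosome reverse-complemented).
#'
#' @param g a `genome`.
#' @param c1,c2 distinct chromosome indices; `c1` keeps its orientation.
#' @param orient `"same"` or `"flip"`.
#' @return `list(genome =, event =)`.
#' @export
apply_fusion <- function(g, c1, c2, orient = c("same", "flip")) {
  orient <- match.arg(orient)
  if (c1 == c2) stop("fusion needs two distinct chromosomes")
  v <- g$chromosomes[[c1]]; w <- g$chromosomes[[c2]]
  if (orient == "same") {
    joined <- c(v, w)
    destroyed <- c(canonical_adjacency(v[length(v)], 0L),
                   canonical_adjacency(0L, w[1L]))
    created <- canonical_adjacency(v[length(v)], w[1L])
  } else {
    joined <- c(v, -rev(w))
    destroyed <- c(canonical_adjacency(v[length(v)], 0L),
                   canonical_adjacency(w[length(w)], 0L))
    created <- canonical_adjacency(v[length(v)], -w[length(w)])
  }
  g$chromosomes[[c1]] <- joined
  g$chromosomes[[c2]] <- NULL
  list(genome = g,
       event = .new_event("fusion", list(c1 = c1, c2 = c2, orient = orient),
                          destroyed, created))
}

#' Apply a fission
#'
#' Splits one chromosome into two at the junction after position `pos`;
#' both parts must be non-empty.
#'
#' @param g a `genome`.
#' @param chrom chromosome index.
#' @param pos split after this position, `1 <= pos < length`.
#' @return `list(genome =, event =)`.
#' @export
apply_fission <- function(g, chrom, pos) {
  v <- g$chromosomes[[chrom]]
  if (pos < 1L || pos >= length(v))
    stop("fission position must leave both sides non-empty")
  destroyed <- canonical_adjacency(v[pos], v[pos + 1L])
  created <- c(canonical_adjacency(v[pos], 0L),
               canonical_adjacency(0L, v[pos + 1L]))
  g$chromosomes[[chrom]] <- v[seq_len(pos)]
  g$chromosomes[[length(g$chromosomes) + 1L]] <- v[(pos + 1L):length(v)]
  list(genome = g,
       event = .new_event("fission", list(chrom = chrom, pos = pos),
                          destroyed, created))
}

## GRIMM-style I/O ------------------------------------------------------------

#' Read genomes in GRIMM format
#'
#' Format: a `>name` header per genome, then one chromosome per line as
#' whitespace-separated signed integers terminated by `$` (linear
#' chromosomes).  Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return named list of `genome` objects.
#' @export
read_grimm <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genomes <- list()
  name <- NULL
  chrs <- list()
  flush <- function() {
    if (!is.null(name)) {
      if (length(chrs) == 0L) stop("genome '", name, "' has no chromosomes")
      genomes[[name]] <<- genome(chrs, name = name)
    }
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      name <- trimws(substring(ln, 2L))
      if (!nzchar(name)) stop("empty genome name in GRIMM file")
      if (name %in% names(genomes)) stop("duplicate genome name: ", name)
      chrs <- list()
    } else {
      if (is.null(name)) stop("chromosome line before any '>' header")
      toks <- strsplit(ln, "[[:space:]]+")[[1L]]
      if (toks[length(toks)] != "$")
        stop("chromosome line not terminated by '$': ", ln)
      toks <- toks[-length(toks)]
      if (length(toks) == 0L) stop("empty chromosome line")
      chrs[[length(chrs) + 1L]] <- as.integer(toks)
    }
  }
  flush()
  genomes
}

#' Write genomes in GRIMM format
#'
#' @param genomes list of `genome` objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_grimm <- function(genomes, path) {
  out <- character(0)
  for (g in genomes) {
    out <- c(out, paste0(">", g$name),
             vapply(g$chromosomes,
                    function(v) paste(c(v, "$"), collapse = " "), ""))
  }
  writeLines(out, path)
  invisible(path)
}
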