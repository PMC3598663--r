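## Congener structure, naming and chlorine-site classification.
##
## A chlorophenyl ring is a subset of positions {2,3,4,5,6}; carbon 1 bears
## the biphenyl bond. A 1-substituted ring has a mirror symmetry mapping
## 2<->6, 3<->5, 4->4, so {3,6} and {2,5} are the same physical pattern; the
## canonical form is the lexicographically smaller of the two images.

HOMOLOGS <- c("mono", "di", "tri", "tetra", "penta", "hexa", "hepta",
              "octa", "nona", "deca")

.ringString <- function(positions) paste0(sort(positions), collapse = "")

.ringFromString <- function(s) {
  if (!nzchar(s)) return(integer(0))
  as.integer(strsplit(s, "")[[1]])
}

.mirrorRing <- function(positions) sort(8L - positions)

#' Canonicalize a ring substitution pattern
#'
#' Reduces a set of chlorine positions on one phenyl ring to its canonical
#' form under the ring mirror symmetry (2<->6, 3<->5, 4 fixed): the
#' lexicographically smaller of the sorted pattern and its mirror image.
#' Canonicalization is idempotent. Exactly 20 canonical patterns exist,
#' including the empty (unsubstituted) ring.
#'
#' @param positions integer vector of chlorine positions, subset of 2..6
#'   (duplicates rejected); may be empty.
#' @return sorted integer vector, the canonical pattern.
#' @examples
#' canonicalizeRing(c(3, 6))    # 2 5 : the mirror image sorts smaller
#' canonicalizeRing(c(2, 5, 6)) # 2 3 6
#' @export
canonicalizeRing <- function(positions) {
  positions <- as.integer(positions)
  if (length(positions) == 0L) return(integer(0))
  if (!all(positions %in% 2:6))
    stop("ring positions must lie in 2..6, got: ",
         paste(positions[!positions %in% 2:6], collapse = ", "))
  if (anyDuplicated(positions))
    stop("duplicate ring position: ",
         paste(unique(positions[duplicated(positions)]), collapse = ", "))
  a <- sort(positions)
  b <- .mirrorRing(positions)
  if (.ringString(b) < .ringString(a)) b else a
}

#' All canonical ring patterns
#'
#' @return character vector of the 20 canonical ring strings ("" is the
#'   unsubstituted ring), sorted by chlorine count then string.
#' @export
allRingPatterns <- function() {
  pats <- character(0)
  for (k in 0:5) {
    if (k == 0) { pats <- c(pats, ""); next }
    combos <- utils::combn(2:6, k, simplify = FALSE)
    pats <- c(pats, vapply(combos, function(x) .ringString(canonicalizeRing(x)),
                           character(1)))
  }
  pats <- unique(pats)
  pats[order(nchar(pats), pats)]
}

## Canonical ring ordering for a congener: more chlorines first; on ties the
## numerically/lexicographically smaller position string first. This is the
## single naming authority; it reproduces every printed name ("245-24-CB",
## "24-25-CB", "235-245-CB").
.orderRings <- function(ra, rb) {
  sa <- .ringString(ra); sb <- .ringString(rb)
  if (length(ra) > length(rb)) list(ra, rb)
  else if (length(rb) > length(ra)) list(rb, ra)
  else if (sa <= sb) list(ra, rb)
  else list(rb, ra)
}

.newCongener <- function(ringA, ringB) {
  ra <- canonicalizeRing(ringA)
  rb <- canonicalizeRing(ringB)
  o <- .orderRings(ra, rb)
  n <- length(ra) + length(rb)
  if (n < 1L) stop("a congener must carry at least one chlorine")
  name <- if (length(o[[2]]) == 0L) paste0(.ringString(o[[1]]), "-CB")
          else paste0(.ringString(o[[1]]), "-", .ringString(o[[2]]), "-CB")
  methods::new("Congener", ringA = o[[1]], ringB = o[[2]], name = name,
               nChlorines = as.integer(n), homolog = HOMOLOGS[n])
}

#' Parse a congener name
#'
#' Parses the per-ring positional dialect used throughout the congener
#' tables: \code{"<digits>-<digits>-CB"}, digits in 2--6, or
#' \code{"<digits>-CB"} for congeners chlorinated on a single ring. The
#' result is canonical: rings are mirror-normalized and ordered (more
#' chlorines first, ties broken by the smaller position string), so parsing
#' and re-rendering any canonical printed name returns the same string.
#'
#' @param name congener name string, e.g. \code{"2345-245-CB"}.
#' @return a \code{\linkS4class{Congener}}.
#' @examples
#' parseCongener("2345-245-CB")
#' parseCongener("2345-CB")     # single-ring tetrachlorobiphenyl
#' @export
parseCongener <- function(name) {
  if (length(name) != 1L || !is.character(name))
    stop("'name' must be a single character string")
  hit <- .cacheGet(paste0("cong|", name))
  if (!is.null(hit)) return(hit)
  if (!grepl("-CB$", name))
    stop("malformed congener name (missing -CB suffix): '", name, "'")
  body <- sub("-CB$", "", name)
  toks <- strsplit(body, "-", fixed = TRUE)[[1]]
  if (length(toks) < 1L || length(toks) > 2L || any(!nzchar(toks)))
    stop("malformed congener name: '", name, "'")
  rings <- lapply(toks, function(tok) {
    if (grepl("[^2-6]", tok))
      stop("invalid ring token '", tok, "' in '", name,
           "': positions must be digits 2-6")
    pos <- .ringFromString(tok)
    if (anyDuplicated(pos))
      stop("duplicate position in ring token '", tok, "' of '", name, "'")
    pos
  })
  if (length(rings) == 1L) rings[[2]] <- integer(0)
  .cacheSet(paste0("cong|", name), .newCongener(rings[[1]], rings[[2]]))
}

.asCongener <- function(x) {
  if (methods::is(x, "Congener")) x else parseCongener(x)
}

#' @rdname parseCongener
#' @param x a \code{Congener} or a name string.
#' @return \code{congenerName} returns the canonical name string.
#' @export
congenerName <- function(x) .asCongener(x)@name

#' Accessors for congener structure
#'
#' @param x a \code{\linkS4class{Congener}} or a congener name string.
#' @return \code{nChlorines}: total chlorine count. \code{homolog}: homolog
#'   class string. \code{ringPatterns}: list of the two canonical ring
#'   position vectors.
#' @export
nChlorines <- function(x) .asCongener(x)@nChlorines

#' @rdname nChlorines
#' @export
homolog <- function(x) .asCongener(x)@homolog

#' @rdname nChlorines
#' @export
ringPatterns <- function(x) {
  cg <- .asCongener(x)
  list(cg@ringA, cg@ringB)
}

#' Enumerate all PCB congeners
#'
#' Exhaustively enumerates the distinct chlorinated biphenyls: unordered
#' pairs of canonical ring patterns carrying at least one chlorine in total.
#' There are exactly 209, partitioning by homolog as mono 3, di 12, tri 24,
#' tetra 42, penta 46, hexa 42, hepta 24, octa 12, nona 3, deca 1.
#'
#' @param homolog optional homolog class (\code{"mono"} ... \code{"deca"})
#'   to filter by.
#' @return character vector of canonical congener names, ordered by chlorine
#'   count then name.
#' @examples
#' length(enumerateAllCongeners())          # 209
#' enumerateAllCongeners(homolog = "deca")  # "23456-23456-CB"
#' @export
enumerateAllCongeners <- function(homolog = NULL) {
  full <- .cacheGet("enum|all")
  if (is.null(full)) {
    pats <- allRingPatterns()
    out <- character(0)
    ncl <- integer(0)
    for (i in seq_along(pats)) {
      for (j in i:length(pats)) {
        na <- nchar(pats[i]); nb <- nchar(pats[j])
        if (na + nb == 0L) next
        cg <- .newCongener(.ringFromString(pats[i]), .ringFromString(pats[j]))
        out <- c(out, cg@name)
        ncl <- c(ncl, cg@nChlorines)
      }
    }
    stopifnot(!anyDuplicated(out))
    ord <- order(ncl, out)
    full <- .cacheSet("enum|all", list(out = out[ord], ncl = ncl[ord]))
  }
  out <- full$out; ncl <- full$ncl
  if (!is.null(homolog)) {
    homolog <- match.arg(homolog, HOMOLOGS)
    out <- out[ncl == match(homolog, HOMOLOGS)]
  }
  out
}

#' Classify the chlorine sites of a congener
#'
#' Assigns each chlorine its position class relative to the biphenyl bond
#' (ortho = 2,6; meta = 3,5; para = 4) and its flanking state. A chlorine at
#' position p is flanked by a chlorine at p-1 or p+1 on the same ring,
#' counting only positions in 2..6 (carbon 1 never flanks), so position 2
#' can only be flanked from 3, position 6 only from 5, and positions 2/6 can
#' never be doubly flanked.
#'
#' @param x a \code{\linkS4class{Congener}} or name string.
#' @return data.frame with columns \code{ring} (1 or 2), \code{position},
#'   \code{class} and \code{flanking} (\code{"unflanked"},
#'   \code{"singly_flanked"} or \code{"doubly_flanked"}), one row per
#'   chlorine.
#' @examples
#' classifyChlorines("2345-CB")
#' @export
classifyChlorines <- function(x) {
  cg <- .asCongener(x)
  one <- function(ring, idx) {
    if (!length(ring)) return(NULL)
    data.frame(
      ring = idx,
      position = ring,
      class = c("2" = "ortho", "3" = "meta", "4" = "para", "5" = "meta",
                "6" = "ortho")[as.character(ring)],
      flanking = vapply(ring, function(p) {
        nb <- intersect(c(p - 1L, p + 1L), 2:6)
        k <- sum(nb %in% ring)
        c("unflanked", "singly_flanked", "doubly_flanked")[k + 1L]
      }, character(1)),
      row.names = NULL
    )
  }
  rbind(one(cg@ringA, 1L), one(cg@ringB, 2L))
}

#' Molecular weight of a congener
#'
#' Biphenyl skeleton mass plus one H-to-Cl substitution increment per
#' chlorine: 154.21 + n * 34.44 g/mol (34.44 = 35.45 - 1.008, rounded).
#' Homolog pseudo-names (\code{"hexa-CB"}) are accepted, since molecular
#' weight depends only on the chlorine count.
#'
#' @param x congener name(s), homolog pseudo-name(s), or a \code{Congener}.
#' @return numeric vector of masses in g/mol.
#' @examples
#' molecularWeight("245-245-CB")  # 360.85
#' @export
molecularWeight <- function(x) {
  if (methods::is(x, "Congener")) return(154.21 + x@nChlorines * 34.44)
  n <- vapply(x, .entryChlorines, numeric(1))
  unname(154.21 + n * 34.44)
}

## Chlorine count for a profile entry name: canonical congener name or a
## homolog pseudo-name like "hexa-CB".
.isHomologName <- function(name) tolower(sub("-CB$", "", name)) %in% HOMOLOGS

.entryChlorines <- function(name) {
  base <- tolower(sub("-CB$", "", name))
  i <- match(base, HOMOLOGS)
  if (!is.na(i)) return(as.numeric(i))
  as.numeric(nChlorines(name))
}

.entryHomolog <- function(name) {
  base <- tolower(sub("-CB$", "", name))
  if (base %in% HOMOLOGS) return(base)
  homolog(name)
}

## Canonical form of a profile entry name (congener canonicalized, homolog
## pseudo-names lower-cased).
.canonicalEntryName <- function(name) {
  if (.isHomologName(name)) paste0(tolower(sub("-CB$", "", name)), "-CB")
  else congenerName(name)
}

setMethod("show", "Congener", function(object) {
  cat(sprintf("PCB congener %s (%s-CB, %d Cl, %.2f g/mol)\n",
              object@name, object@homolog, object@nChlorines,
              154.21 + object@nChlorines * 34.44))
})
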