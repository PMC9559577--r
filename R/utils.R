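## Internal helpers shared across modules.

# Molecule kinds and the four admissible endpoint-type pairs. Same-kind
# miRNA or lncRNA pairs are never admitted.
.MOLECULE_KINDS <- c("gene", "miRNA", "lncRNA")

# Canonical edge-kind label for a pair of endpoint kinds, or NA_character_
# when the pair is not admissible. Vectorized over both arguments.
.edgeKind <- function(kindA, kindB) {
  lo <- pmin(match(kindA, .MOLECULE_KINDS), match(kindB, .MOLECULE_KINDS))
  hi <- pmax(match(kindA, .MOLECULE_KINDS), match(kindB, .MOLECULE_KINDS))
  key <- paste(lo, hi, sep = "-")
  unname(c("1-1" = "gene-gene", "2-3" = "miRNA-lncRNA",
           "1-2" = "gene-miRNA", "1-3" = "gene-lncRNA")[key])
}

# Numeric index of a stage label "S<k>".
.stageNum <- function(stage) {
  if (!all(grepl("^S[0-9]+$", stage)))
    stop("stage labels must have the form 'S<k>', got: ",
         paste(stage, collapse = ", "))
  as.integer(sub("^S", "", stage))
}

# Deterministic 31-bit seed derived from arbitrary components, so that each
# walk owns an RNG substream independent of execution order. Polynomial
# rolling hash over the UTF-8 bytes of the collapsed key; all intermediates
# stay below 2^53 so double arithmetic is exact.
.hashSeed <- function(...) {
  key <- paste(vapply(list(...), paste, "", collapse = "\r"), collapse = "\x1f")
  h <- 0
  p <- 2147483647  # 2^31 - 1
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% p
  as.integer(h)
}

#' Jaccard coefficient of two sets
#'
#' \code{|A intersect B| / |A union B|}, the similarity used throughout the
#' package: to connect modules of adjacent stages, to connect enriched
#' functions sharing annotated genes, and to filter core evolution edges.
#' Two empty sets have coefficient 0 by convention.
#'
#' @param a,b vectors interpreted as sets (duplicates ignored).
#' @return A number in \code{[0, 1]}.
#' @examples
#' jaccardCoefficient(c("a", "b"), c("b", "c"))  # 1/3
#' @export
jaccardCoefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}
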