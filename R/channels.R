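# 96-channel single-base-substitution classification.
#
# Channels are pyrimidine-collapsed: every substitution is expressed with a
# C or T reference (purine-reference calls are reverse-complemented together
# with their flanks). Channel order is a documented constant: the six
# substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each crossed with the
# 16 flank combinations in lexicographic (5' x 3') order.

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' The fixed 96-channel label order
#'
#' Labels have the form `"X[R>A]Y"` with `R` the pyrimidine reference
#' (C or T), `A` the alternate base, and `X`/`Y` the 5'/3' flanking bases.
#' Substitution classes are ordered C>A, C>G, C>T, T>A, T>C, T>G; within a
#' class the 16 flank pairs are lexicographic. Serialized catalogs always use
#' this order, so they are bit-stable.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(.BASES, .BASES, function(x, y) {
      paste0(x, "[", s, "]", y)
    })))
  }), use.names = FALSE)
}

# reverse complement of a short uppercase DNA string (vectorized over strings)
revcomp <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    paste(rev(unname(.COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

#' Classify a single-base substitution into its 96-channel label
#'
#' Purine-reference mutations (ref A or G) are reverse-complemented — bases
#' and flank order — so that every channel carries a pyrimidine reference.
#'
#' @param ref,alt Single reference/alternate bases (A/C/G/T). Vectorized.
#' @param context3 3-base uppercase context centered on the mutated base;
#'   its middle base must equal `ref`.
#' @return Channel label(s), e.g. `"A[C>T]A"`.
#' @examples
#' classify_channel("C", "T", "ACA") # "A[C>T]A"
#' classify_channel("G", "A", "TGT") # "A[C>T]A" (reverse-complemented)
#' @export
classify_channel <- function(ref, alt, context3) {
  n <- max(length(ref), length(alt), length(context3))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context3 <- rep_len(toupper(context3), n)
  ok_base <- ref %in% .BASES & alt %in% .BASES & nchar(ref) == 1L & nchar(alt) == 1L
  if (!all(ok_base) || any(ref == alt)) {
    stop("classify_channel() handles single-base substitutions only ",
         "(ref/alt must be single distinct bases)", call. = FALSE)
  }
  if (any(nchar(context3) != 3L)) {
    stop("context3 must be a 3-base string", call. = FALSE)
  }
  mid <- substr(context3, 2L, 2L)
  if (any(mid != ref)) {
    stop("context error: middle base of context3 does not match ref",
         call. = FALSE)
  }
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    ref[flip] <- unname(.COMPLEMENT[ref[flip]])
    alt[flip] <- unname(.COMPLEMENT[alt[flip]])
    context3[flip] <- revcomp(context3[flip])
  }
  paste0(substr(context3, 1L, 1L), "[", ref, ">", alt, "]",
         substr(context3, 3L, 3L))
}
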