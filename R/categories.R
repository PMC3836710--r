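# The six strand-symmetric base-change categories.
#
# The 12 directed changes partition into 6 categories, each pooling a
# change with its reverse-complement twin (A>G with T>C, etc.). The
# source state of a category is W (A/T) or S (G/C); weak-to-strong
# changes gain GC, strong-to-weak changes lose it, and two categories
# (A:T>T:A, G:C>C:G) conserve GC content.

#' @rdname categorize_substitution
#' @format NULL
#' @export
CATEGORY_LEVELS <- c("A:T>G:C", "A:T>C:G", "A:T>T:A",
                     "G:C>A:T", "G:C>T:A", "G:C>C:G")

# category index by (anc, der) integer base codes (A=1,C=2,G=3,T=4)
.category_matrix <- local({
  m <- matrix(NA_integer_, 4, 4)
  m[1, 3] <- m[4, 2] <- 1L   # A>G, T>C
  m[1, 2] <- m[4, 3] <- 2L   # A>C, T>G
  m[1, 4] <- m[4, 1] <- 3L   # A>T, T>A
  m[3, 1] <- m[2, 4] <- 4L   # G>A, C>T
  m[3, 4] <- m[2, 1] <- 5L   # G>T, C>A
  m[3, 2] <- m[2, 3] <- 6L   # G>C, C>G
  m
})

#' Strand-symmetric base-change category of a substitution
#'
#' Maps a directed ancestral-to-derived change to one of the six
#' strand-symmetric categories; a change and its reverse complement share
#' a category.
#'
#' @param anc,der Character vectors of single bases (`A/C/G/T`);
#'   recycled.
#' @return Factor with levels `CATEGORY_LEVELS`.
#' @examples
#' categorize_substitution(c("A", "T", "C", "G"), c("G", "C", "T", "C"))
#' @export
categorize_substitution <- function(anc, der) {
  a <- match(toupper(anc), BASES)
  d <- match(toupper(der), BASES)
  if (anyNA(a) || anyNA(d))
    stop("categorize_substitution: bases must be A, C, G or T")
  if (any(a == d))
    stop("categorize_substitution: anc and der must differ")
  factor(CATEGORY_LEVELS[.category_matrix[cbind(a, d)]],
         levels = CATEGORY_LEVELS)
}

#' Source state (W or S) of a category
#' @param category Category label(s) from `CATEGORY_LEVELS`, or the
#'   pooled labels `"W>S"` / `"S>W"`.
#' @return `"W"` or `"S"` per element.
#' @export
category_source_state <- function(category) {
  ifelse(startsWith(as.character(category), "A:T") |
           as.character(category) == "W>S", "W", "S")
}

# expand a category label (one of the six, or pooled "W>S"/"S>W") to its
# member single-category labels
expand_category <- function(category) {
  category <- as.character(category)
  if (category == "W>S") return(CATEGORY_LEVELS[1:2])
  if (category == "S>W") return(CATEGORY_LEVELS[4:5])
  if (!category %in% CATEGORY_LEVELS)
    stop("unknown base-change category: ", category)
  category
}
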