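#' Crystallographic space groups
#'
#' Construct a space-group object holding the Hermann-Mauguin symbol and the
#' full list of symmetry operators as (rotation, translation) pairs acting on
#' fractional coordinates. Operators for the groups needed by the packing
#' analysis (P1, P212121, P6522) are tabulated in-package from International
#' Tables; the first operator is always the identity and every rotation part
#' is a proper rotation (determinant +1).
#'
#' @param symbol Hermann-Mauguin symbol. Spacing and subscripts are
#'   normalised, so `"P 65 2 2"`, `"P6522"` and `"P 65 22"` are equivalent.
#' @return An object of class `space_group`: a list with elements `symbol`
#'   (normalised string) and `ops`, a list of lists each holding `R` (3x3
#'   integer matrix over fractional axes) and `t` (length-3 fractional
#'   translation in `[0, 1)`).
#' @examples
#' sg <- space_group("P 21 21 21")
#' length(sg$ops)  # 4
#' @export
space_group <- function(symbol) {
  key <- normalize_sg_symbol(symbol)
  ops <- switch(key,
    "P 1"         = list("x,y,z"),
    "P 21 21 21"  = list("x,y,z", "-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z",
                         "-x,y+1/2,-z+1/2"),
    "P 65 2 2"    = list("x,y,z", "x-y,x,z+5/6", "-y,x-y,z+2/3", "-x,-y,z+1/2",
                         "-x+y,-x,z+1/3", "y,-x+y,z+1/6", "-y,-x,-z+1/6",
                         "-x,-x+y,-z+1/3", "-x+y,y,-z+1/2", "y,x,-z+2/3",
                         "x,x-y,-z+5/6", "x-y,-y,-z"),
    stop_bad(paste0(
      "unsupported space-group symbol '%s'; supported symbols: ",
      "P 1, P 21 21 21, P 65 2 2"), symbol)
  )
  structure(list(symbol = key, ops = lapply(ops, parse_symop)),
            class = "space_group")
}

# "P6522", "P 65 22", "P 65 2 2" -> "P 65 2 2"; "P212121" -> "P 21 21 21".
normalize_sg_symbol <- function(symbol) {
  s <- toupper(gsub("[[:space:]_]", "", symbol))
  switch(s,
    "P1"       = "P 1",
    "P212121"  = "P 21 21 21",
    "P6522"    = "P 65 2 2",
    symbol)
}

# Parse a triplet like "-x+y,-x,z+1/3" into R (3x3) and t (length 3).
parse_symop <- function(triplet) {
  parts <- strsplit(gsub("[[:space:]]", "", triplet), ",")[[1]]
  stopifnot(length(parts) == 3L)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  axes <- c(x = 1L, y = 2L, z = 3L)
  for (i in 1:3) {
    expr <- parts[i]
    # split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (term in terms) {
      sign <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (grepl("^[xyz]$", body)) {
        R[i, axes[[body]]] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        num <- as.numeric(strsplit(body, "/")[[1]])
        t[i] <- t[i] + sign * num[1] / num[2]
      } else {
        stop_bad("cannot parse symmetry operator term '%s'", term)
      }
    }
  }
  list(R = R, t = t %% 1)
}

#' @export
print.space_group <- function(x, ...) {
  cat("Space group", x$symbol, "with", length(x$ops), "operators\n")
  invisible(x)
}
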