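#' Cell-type taxonomy for TRAP-stained osteoclast cultures
#'
#' Four morphological classes are distinguished in a TRAP-stained culture
#' well: `"preosteoclast"` (TRAP+ cells with 1-2 nuclei), `"osteoclast_i"`
#' (classical osteoclasts, 3-14 nuclei), `"osteoclast_ii"` (giant cells
#' with 15 or more nuclei), and `"ghost"` (vanished cells recognizable
#' only by their faint silhouette). The three TRAP+ classes are ordered by
#' minimum nucleus count.
#'
#' @format A character vector of the four canonical class names.
#' @export
CELL_TYPES <- c("preosteoclast", "osteoclast_i", "osteoclast_ii", "ghost")

# Minimum nucleus count per TRAP+ class; the in vitro convention defines an
# osteoclast as a TRAP+ cell with >= 3 nuclei, and "giant" type II cells
# start at 15.
.NUCLEI_MIN <- c(preosteoclast = 1L, osteoclast_i = 3L, osteoclast_ii = 15L)

#' Classify a cell by nucleus count
#'
#' Maps an annotated nucleus count to the cell-type taxonomy: 1-2 nuclei is
#' a preosteoclast, 3-14 a type I osteoclast, 15 or more a type II
#' ("giant") osteoclast. A ghost flag dominates: ghost cells are classified
#' by their silhouette, not their (usually unknown) nucleus count.
#'
#' @param n_nuclei Nonnegative integer nucleus count. May be `NA` only when
#'   `is_ghost` is `TRUE`.
#' @param is_ghost Logical; `TRUE` for a vanished (ghost) cell.
#' @return One of [CELL_TYPES].
#' @examples
#' classify_cell_type(2)            # "preosteoclast"
#' classify_cell_type(3)            # "osteoclast_i"
#' classify_cell_type(15)           # "osteoclast_ii"
#' classify_cell_type(7, is_ghost = TRUE)  # "ghost"
#' @export
classify_cell_type <- function(n_nuclei, is_ghost = FALSE) {
  stopifnot(length(n_nuclei) == 1L, length(is_ghost) == 1L)
  if (isTRUE(is_ghost)) {
    return("ghost")
  }
  if (is.na(n_nuclei) || n_nuclei < 1 || n_nuclei != floor(n_nuclei)) {
    stop("invalid annotation: a TRAP+ cell must have a nucleus count >= 1 (got ",
         deparse(n_nuclei), ")")
  }
  if (n_nuclei <= 2) {
    "preosteoclast"
  } else if (n_nuclei <= 14) {
    "osteoclast_i"
  } else {
    "osteoclast_ii"
  }
}

as_cell_type <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), CELL_TYPES)
  if (length(bad) > 0) {
    stop("unknown cell type(s): ", paste(bad, collapse = ", "))
  }
  x
}
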