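#' Test whether two planar segments properly cross
#'
#' A barrier blocks line of sight only when the sight line crosses its
#' interior; contacts at a single endpoint (zero-measure touches) do not
#' block. All coordinates are metres.
#'
#' @param p1,p2 numeric length-2, endpoints of the first (sight) segment.
#' @param q1,q2 numeric length-2, endpoints of the second (barrier) segment.
#' @return logical scalar.
#' @keywords internal
segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  o1 <- orient(p1, p2, q1)
  o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1)
  o4 <- orient(q1, q2, p2)
  # strict crossing of both open segments
  o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

#' Line-of-sight predicate between two points given barriers
#'
#' @param a,b numeric length-2 points (metres).
#' @param barriers data frame with columns `x1,y1,x2,y2`, possibly empty.
#' @return TRUE when no barrier segment crosses the open segment a-b.
#' @keywords internal
has_line_of_sight <- function(a, b, barriers) {
  if (is.null(barriers) || nrow(barriers) == 0L) return(TRUE)
  for (i in seq_len(nrow(barriers))) {
    if (segments_cross(a, b,
                       c(barriers$x1[i], barriers$y1[i]),
                       c(barriers$x2[i], barriers$y2[i]))) {
      return(FALSE)
    }
  }
  TRUE
}
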