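speaker_colours <- function(channels, carer_channel = "CS") {
  cols <- ifelse(channels == carer_channel, "#3B6FB6", "#C0392B")
  stats::setNames(cols, channels)
}

#' Render a turn-by-turn recurrence plot
#'
#' Draws the lower-triangular recurrence grid: diagonal cells are coloured by
#' speaker (blue for the carer channel, red for the partner), off-diagonal
#' cells are shaded by pairwise similarity, with a two-colour split showing
#' the speakers of the two turns involved (cross-speaker recurrence appears
#' as a red/blue split, self-recurrence as a single colour). Behaviour code
#' labels, when a conversation is supplied, are overlaid next to their turn.
#'
#' @param m A [recurrence_matrix()].
#' @param conv Optional matching `conversation`, used for behaviour labels.
#' @param file Optional output path; `.png` or `.svg` selects the device,
#'   otherwise the current device is used.
#' @param carer_channel Channel drawn in blue.
#' @param show_codes Logical; overlay behaviour code labels.
#' @param min_alpha Opacity floor for nonzero similarities so weak
#'   recurrence stays visible.
#' @param width,height Device size in inches when `file` is given.
#' @return `file` (or `NULL`), invisibly.
#' @export
render_recurrence_plot <- function(m, conv = NULL, file = NULL,
                                   carer_channel = "CS", show_codes = TRUE,
                                   min_alpha = 0.25, width = 7, height = 7) {
  stopifnot(inherits(m, "recurrence_matrix"))
  if (!is.null(conv)) stopifnot(inherits(conv, "conversation"))
  dev_open <- FALSE
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "png") {
      grDevices::png(file, width = width, height = height, units = "in",
                     res = 150)
    } else if (ext == "svg") {
      grDevices::svg(file, width = width, height = height)
    } else {
      grDevices::pdf(file, width = width, height = height)
    }
    dev_open <- TRUE
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  n <- m$n_turns
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::title(main = m$conversation_id)
  if (n == 0L) return(invisible(file))
  graphics::plot.window(xlim = c(0, n), ylim = c(-n, 0), asp = 1)
  cols <- speaker_colours(m$speaker, carer_channel)
  shade <- function(col, alpha) grDevices::adjustcolor(col, alpha.f = alpha)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      x0 <- j - 1; x1 <- j; y0 <- -i; y1 <- -(i - 1)
      if (i == j) {
        graphics::rect(x0, y0, x1, y1, col = cols[i], border = "white",
                       lwd = 0.3)
      } else if (m$sim[i, j] > 0) {
        al <- min_alpha + (1 - min_alpha) * m$sim[i, j]
        # split cell: earlier turn's colour upper-left, later turn's lower-right
        graphics::polygon(c(x0, x1, x0), c(y1, y1, y0),
                          col = shade(cols[j], al), border = NA)
        graphics::polygon(c(x1, x1, x0), c(y1, y0, y0),
                          col = shade(cols[i], al), border = NA)
        graphics::rect(x0, y0, x1, y1, border = "grey85", lwd = 0.3)
      }
    }
  }
  if (show_codes && !is.null(conv) && length(conv$codes) == n) {
    lab <- vapply(conv$codes, paste, "", collapse = ",")
    has <- nzchar(lab)
    if (any(has))
      graphics::text(seq_len(n)[has] + 0.15, -(seq_len(n)[has] - 1) + 0.35,
                     lab[has], adj = 0, cex = 0.5, xpd = NA)
  }
  invisible(file)
}

#' @export
plot.recurrence_matrix <- function(x, conv = NULL, ...) {
  render_recurrence_plot(x, conv = conv, ...)
}

#' @export
plot.recurrence_analysis <- function(x, ...) {
  render_recurrence_plot(x$matrix, conv = x$conversation, ...)
}
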