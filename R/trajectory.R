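# Trajectory container: a time grid with model states plus derived columns.

#' Build a sweep trajectory from transformed coordinates
#'
#' Assembles the standard trajectory table from time points and the
#' `(x, p1, p2)` states, filling in the gamete frequencies, linkage
#' disequilibrium, the frequency `p_A` of allele `A` and its heterozygosity
#' `H`. Deterministic integrations are reported in generations; the
#' diffusion module works in units of `2N` generations, and the
#' `time_scale` attribute (`"generations"` or `"diffusion_2N"`) records
#' which applies.
#'
#' @param times Strictly increasing numeric vector of time points.
#' @param x,p1,p2 Numeric vectors of the same length as `times`.
#' @param time_scale `"generations"` or `"diffusion_2N"`.
#' @return A data frame of class `"sweep_trajectory"` with columns
#'   `time, x1, x2, x3, x4, x, p1, p2, D, p_A, H` and attribute
#'   `time_scale`.
#' @examples
#' sweep_trajectory(0:2, c(.1, .2, .3), c(.5, .5, .5), c(.5, .5, .5))
#' @export
sweep_trajectory <- function(times, x, p1, p2,
                             time_scale = c("generations", "diffusion_2N")) {
  time_scale <- match.arg(time_scale)
  n <- length(times)
  if (length(x) != n || length(p1) != n || length(p2) != n)
    stop("times, x, p1, p2 must have equal length")
  if (n > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  x1 <- p1 * x
  x2 <- (1 - p1) * x
  x3 <- p2 * (1 - x)
  x4 <- (1 - p2) * (1 - x)
  p_A <- p1 * x + p2 * (1 - x)
  out <- data.frame(time = times, x1 = x1, x2 = x2, x3 = x3, x4 = x4,
                    x = x, p1 = p1, p2 = p2,
                    D = x * (1 - x) * (p1 - p2),
                    p_A = p_A, H = 2 * p_A * (1 - p_A))
  attr(out, "time_scale") <- time_scale
  class(out) <- c("sweep_trajectory", "data.frame")
  out
}

#' @export
print.sweep_trajectory <- function(x, ...) {
  cat(sprintf("Sweep trajectory: %d time points (%s), x from %.4g to %.4g\n",
              nrow(x), attr(x, "time_scale"), x$x[1], x$x[nrow(x)]))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Write / read a trajectory as TSV
#'
#' Plain tab-separated text with fixed column order
#' `time time_scale x1 x2 x3 x4 x p1 p2 D p_A H` and floating values printed
#' at 10 significant digits, one row per recorded time point.
#'
#' @param traj A [sweep_trajectory()].
#' @param path Output (input) file path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns a `"sweep_trajectory"`.
#' @examples
#' tr <- sweep_trajectory(0:2, c(.1, .2, .3), c(.5, .5, .5), c(.5, .5, .5))
#' f <- tempfile(fileext = ".tsv")
#' write_trajectory(tr, f)
#' read_trajectory(f)
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "sweep_trajectory"))
    stop("traj must be a 'sweep_trajectory'")
  df <- as.data.frame(traj)
  num_cols <- setdiff(names(df), "time_scale")
  out <- data.frame(time = sprintf("%.10g", df$time),
                    time_scale = attr(traj, "time_scale"),
                    stringsAsFactors = FALSE)
  for (cl in setdiff(num_cols, "time")) out[[cl]] <- sprintf("%.10g", df[[cl]])
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ts <- unique(df$time_scale)
  if (length(ts) != 1) stop("trajectory file mixes time scales")
  sweep_trajectory(df$time, df$x, df$p1, df$p2, time_scale = ts)
}
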