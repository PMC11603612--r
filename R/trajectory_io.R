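#' Write a trajectory to a tab-separated file
#'
#' Columns: step, time_ps, one column per lambda coordinate, per-group
#' instantaneous temperatures (prefixed \code{T_}) and per-term energies
#' (prefixed \code{E_}).  Run metadata is stored as '#'-prefixed key=value
#' header lines at full float precision, so a write/read round trip is
#' lossless.
#'
#' @param traj a \code{lambda_trajectory}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "lambda_trajectory"))
  md <- traj$metadata
  num <- function(x) sprintf("%.17g", x)
  hdr <- c(
    paste0("# pH=", num(md$pH)),
    paste0("# seed=", if (is.null(md$seed)) "NA" else md$seed),
    paste0("# mode=", md$mode),
    paste0("# T_physical=", num(md$T_physical)),
    paste0("# dt=", num(md$dt)),
    paste0("# sample_stride=", md$sample_stride),
    paste0("# n_steps=", md$n_steps),
    paste0("# sites=", paste(md$sites, collapse = ",")),
    paste0("# lambda_T=", paste(num(md$lambda_T), collapse = ",")),
    paste0("# lam_site=", paste(md$lam_site, collapse = ",")))
  tab <- cbind(step = traj$step, time_ps = traj$time_ps, traj$lambda,
               `colnames<-`(traj$temps, paste0("T_", colnames(traj$temps))),
               `colnames<-`(traj$energies, paste0("E_", colnames(traj$energies))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Fails closed: a missing required metadata key (such as pH), a malformed
#' header or a column-count mismatch raises an error naming the problem.
#'
#' @param path trajectory file path.
#' @return a \code{lambda_trajectory}.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  mdl <- grep("^# ", lines, value = TRUE)
  md <- list()
  for (l in mdl) {
    kv <- sub("^# ", "", l)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stop(sprintf("malformed metadata line: '%s'", l))
    md[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  for (k in c("pH", "mode", "T_physical", "dt", "sample_stride", "sites",
              "lambda_T", "lam_site"))
    if (is.null(md[[k]]))
      stop(sprintf("trajectory file missing required metadata key '%s'", k))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("trajectory file has no data rows")
  cn <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(cn))
  if (length(bad))
    stop(sprintf("column-count mismatch at line %d",
                 length(mdl) + 1L + bad[1]))
  m <- matrix(as.numeric(unlist(rows)), nrow = length(rows),
              ncol = length(cn), byrow = TRUE)
  colnames(m) <- cn
  lam_cols <- !(cn %in% c("step", "time_ps")) & !startsWith(cn, "T_") &
    !startsWith(cn, "E_")
  seed_chr <- md$seed
  structure(list(
    step = as.integer(m[, "step"]), time_ps = m[, "time_ps"],
    lambda = m[, lam_cols, drop = FALSE],
    env = NULL, gate = NULL, s = NULL,
    temps = `colnames<-`(m[, startsWith(cn, "T_"), drop = FALSE],
                         sub("^T_", "", cn[startsWith(cn, "T_")])),
    energies = `colnames<-`(m[, startsWith(cn, "E_"), drop = FALSE],
                            sub("^E_", "", cn[startsWith(cn, "E_")])),
    conserved = NULL, final_state = NULL,
    metadata = list(
      pH = as.numeric(md$pH),
      seed = if (is.null(seed_chr) || seed_chr == "NA") NULL
             else as.integer(seed_chr),
      mode = md$mode,
      T_physical = as.numeric(md$T_physical),
      dt = as.numeric(md$dt),
      sample_stride = as.integer(md$sample_stride),
      n_steps = if (is.null(md$n_steps)) NA_integer_ else as.integer(md$n_steps),
      sites = strsplit(md$sites, ",", fixed = TRUE)[[1]],
      lambda_T = as.numeric(strsplit(md$lambda_T, ",", fixed = TRUE)[[1]]),
      lam_site = as.integer(strsplit(md$lam_site, ",", fixed = TRUE)[[1]]))),
    class = "lambda_trajectory")
}
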