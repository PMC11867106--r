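#' Read an ultrametric time tree from a newick file
#'
#' Branch lengths must be in time units. The tree must be rooted and
#' binary; node ages are computed from tip-to-root path lengths and the
#' tree must be ultrametric to within `tol` times its height (estimated
#' timetrees carry rounding noise; exact simulator output passes at any
#' tolerance). Square-bracket comments are stripped with a warning.
#'
#' @param path Path to a newick file.
#' @param tol Relative ultrametricity tolerance.
#' @return An `ape::phylo`; pipe into [ltt_from_tree()] for the node
#'   ages.
#' @export
read_newick <- function(path, tol = 1e-6) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (grepl("\\[", txt)) {
    warn("stripping square-bracket comments from newick input.")
    txt <- gsub("\\[[^]]*\\]", "", txt)
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) {
    abort("could not parse newick input.", class = "bdltt_parse_error")
  }
  check_time_tree(tree, tol = tol)
  tree
}

#' @rdname read_newick
#' @param tree A `phylo` (or `sim_tree`, written as its reconstructed
#'   tree).
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "sim_tree")) tree <- prune_to_reconstructed(tree)
  if (!inherits(tree, "phylo")) {
    abort("expected a `phylo` or `sim_tree`.", class = "bdltt_validation_error")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Shared writer: header comment lines ("# key: value") then a TSV body
# with 12 significant digits and deterministic column order.
write_tsv_with_header <- function(df, path, header = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(header)) {
    if (!is.null(header[[k]])) {
      cat(sprintf("# %s: %s\n", k, paste(format(header[[k]]), collapse = " ")),
          file = con)
    }
  }
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' LTT tables on disk
#'
#' LTT data travel as 2-column TSV (`rank`, `age`, ages descending) with
#' `#`-prefixed header comments carrying the stem age and, for simulated
#' data, the seed that regenerates them. Readers and writers round-trip
#' at 12 significant digits.
#'
#' @param data LTT data.
#' @param path File path.
#' @param seed Optional seed to record in the header.
#' @export
write_ltt_tsv <- function(data, path, seed = NULL) {
  data <- as_ltt(data)
  write_tsv_with_header(
    data.frame(rank = data$rank, age = data$age), path,
    header = list(format = "bdltt ltt v1", stem_age = stem_age(data),
                  seed = seed)
  )
}

#' @rdname write_ltt_tsv
#' @export
read_ltt_tsv <- function(path) {
  hdr <- read_header(path)
  df <- utils::read.delim(path, comment.char = "#", sep = "\t")
  if (!"age" %in% names(df)) {
    abort("LTT TSV must have an `age` column.", class = "bdltt_parse_error")
  }
  stem <- if (!is.null(hdr$stem_age)) as.numeric(hdr$stem_age) else NULL
  ltt_data(df$age, stem_age = stem)
}

read_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "# ")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^# ([^:]+): (.*)$", ln))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

#' @rdname write_ltt_tsv
#' @param fit A `bdltt_fit`.
#' @export
write_fit_tsv <- function(fit, path, seed = NULL) {
  df <- as.data.frame(tidy(fit))
  write_tsv_with_header(df, path, header = list(
    format = "bdltt fit v1",
    loglik = fit$loglik,
    status = fit$convergence$status,
    seed = seed
  ))
}

#' @rdname write_ltt_tsv
#' @param surface A [loglik_surface()] result; written long-format
#'   (`lambda0`, `lambda1`, `loglik`).
#' @export
write_surface_tsv <- function(surface, path, seed = NULL) {
  setup <- attr(surface, "setup")
  write_tsv_with_header(surface, path, header = list(
    format = "bdltt surface v1",
    T = setup$T, t0 = setup$t0, survival_p = setup$survival_p,
    seed = seed
  ))
}

#' Rate-model configuration files
#'
#' Rate models round-trip exactly through a small JSON schema (`kind`,
#' rates, change points or knots, `rho`); numbers are written at full
#' precision.
#'
#' @param model A [rate model][make_constant_model] or
#'   [two_epoch_model()].
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "two_epoch_model")) {
    obj <- c(list(kind = "two_epoch"), unclass(model))
  } else {
    stop_not_model(model)
    obj <- unclass(model)
    obj$knots <- model$knots
  }
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$kind)) {
    abort("model config lacks a `kind` field.", class = "bdltt_parse_error")
  }
  switch(obj$kind,
    constant = make_constant_model(obj$lambda, obj$mu, obj$rho),
    piecewise_constant = make_piecewise_model(obj$change_points, obj$lambda,
                                              obj$mu, obj$rho),
    tabulated = make_tabulated_model(obj$knots, obj$lambda, obj$mu, obj$rho),
    two_epoch = two_epoch_model(obj$lambda0, obj$lambda1, T = obj$T,
                                t0 = obj$t0, survival_p = obj$survival_p),
    abort(sprintf("unknown model kind `%s`.", obj$kind),
      class = "bdltt_parse_error")
  )
}
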