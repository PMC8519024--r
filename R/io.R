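# File readers/writers and the command runner behind the command-line
# interface.

detect_delim <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else " "
}

#' Read a numeric matrix from delimited text
#'
#' Comma or tab dialect is auto-detected from the first line (overridable);
#' an optional header row and an optional leading row-name column are
#' detected by non-numeric content.  Rows must be rectangular and the body
#' numeric; violations raise errors naming the offending row and column.
#'
#' @param path File path.
#' @param delim `NULL` (auto), `","`, `"\t"` or `" "`.
#' @param header,rownames `"auto"`, `"yes"` or `"no"`.
#' @return A numeric matrix with dimnames when present in the file.
#' @export
read_matrix <- function(path, delim = NULL, header = "auto",
                        rownames = "auto") {
  header <- match.arg(header, c("auto", "yes", "no"))
  rownames <- match.arg(rownames, c("auto", "yes", "no"))
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("empty input file: %s", path))
  delim <- delim %||% detect_delim(lines[1])
  split_pattern <- if (delim == " ") "[ \t]+" else delim
  cells <- strsplit(lines, split_pattern, fixed = FALSE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    abort(sprintf("ragged input: row %d has %d fields, expected %d",
                  bad, widths[bad], widths[1]))
  }
  is_num <- function(v) !is.na(suppressWarnings(as.numeric(v)))
  first_row_numeric <- all(is_num(cells[[1]]))
  has_header <- switch(header, yes = TRUE, no = FALSE,
                       auto = !first_row_numeric)
  col_names <- NULL
  if (has_header) {
    col_names <- cells[[1]]
    cells <- cells[-1]
    if (length(cells) == 0) abort("no data rows below the header")
  }
  first_col <- vapply(cells, `[[`, character(1), 1L)
  has_rownames <- switch(rownames, yes = TRUE, no = FALSE,
                         auto = !all(is_num(first_col)))
  row_names <- NULL
  if (has_rownames) {
    row_names <- first_col
    cells <- lapply(cells, `[`, -1L)
    if (has_header && length(col_names) == length(cells[[1]]) + 1L) {
      col_names <- col_names[-1L]
    }
  }
  body <- matrix(unlist(cells), nrow = length(cells), byrow = TRUE)
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric cell at row %d, column %d: '%s'",
                  bad[1], bad[2], body[bad[1], bad[2]]))
  }
  dimnames(num) <- list(row_names, col_names)
  num
}

#' Write a numeric matrix as delimited text
#'
#' Values are written with full `%.17g` precision so a write/read round
#' trip reproduces the matrix exactly.
#'
#' @param x Numeric matrix or data frame.
#' @param path Output path.
#' @param delim Field delimiter.
#' @export
write_matrix <- function(x, path, delim = ",") {
  x <- as_design_matrix(x)
  body <- apply(x, 1:2, function(v) sprintf("%.17g", v))
  rows <- apply(body, 1, paste, collapse = delim)
  if (!is.null(colnames(x))) {
    header <- paste(colnames(x), collapse = delim)
    if (!is.null(rownames(x))) header <- paste("row", header, sep = delim)
    rows <- c(header, if (!is.null(rownames(x)))
      paste(rownames(x), rows, sep = delim) else rows)
  } else if (!is.null(rownames(x))) {
    rows <- paste(rownames(x), rows, sep = delim)
  }
  readr::write_lines(rows, path)
  invisible(path)
}

read_response_vector <- function(path, delim = NULL) {
  m <- read_matrix(path, delim = delim)
  if (ncol(m) == 1L) drop(m[, 1]) else
    abort(sprintf("expected a single-column response file, got %d columns",
                  ncol(m)))
}

read_survival_file <- function(path, delim = NULL) {
  m <- read_matrix(path, delim = delim)
  cn <- tolower(colnames(m) %||% character())
  if (all(c("time", "status") %in% cn)) {
    surv_data(m[, which(cn == "time")[1]], m[, which(cn == "status")[1]])
  } else if (ncol(m) == 2L) {
    surv_data(m[, 1], m[, 2])
  } else {
    abort("survival file must have columns time and status")
  }
}

#' Build a run configuration
#'
#' Bundles the options of one command-line style run.  For `tune` exactly
#' the level `alpha` is supplied (the run maps alpha to lambda); for
#' `gt-test` exactly the penalty `lambda` is supplied (the run maps lambda
#' to the smallest level keeping the estimate inside the region).
#'
#' @param command One of `generate`, `tune`, `gt-test`, `cox-tune`,
#'   `criteria`, `simulate`.
#' @param ... Named options: `input`, `response`, `model`, `alpha`,
#'   `lambda`, `test`, `criterion`, `folds`, `grid_size`, `tol`, `seed`,
#'   `out`, `verbose`, and the generator/scenario fields used by
#'   `generate`/`simulate`.
#' @return A `run_config` list.
#' @export
run_config <- function(command, ...) {
  command <- match.arg(command, c("generate", "tune", "gt-test", "cox-tune",
                                  "criteria", "simulate"))
  cfg <- list(command = command, ...)
  if (command == "tune" && (is.null(cfg$alpha) || !is.null(cfg$lambda))) {
    abort("`tune` needs alpha (and not lambda); use gt-test for lambda -> alpha")
  }
  if (command == "gt-test" && (is.null(cfg$lambda) || !is.null(cfg$alpha))) {
    abort("`gt-test` needs lambda (and not alpha); use tune for alpha -> lambda")
  }
  structure(cfg, class = "run_config")
}

# Serialize Inf as the string "inf" so reports are valid JSON.
sanitize_report <- function(x) {
  if (is.list(x)) return(lapply(x, sanitize_report))
  if (is.numeric(x)) {
    out <- as.list(x)
    out <- lapply(out, function(v) if (is.infinite(v)) "inf" else v)
    if (length(out) == 1L) return(out[[1]])
    return(out)
  }
  x
}

write_report <- function(report, out) {
  if (is.null(out)) return(invisible(NULL))
  tmp <- paste0(out, ".tmp")
  jsonlite::write_json(sanitize_report(report), tmp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  file.rename(tmp, out)
  invisible(out)
}

#' Execute one configured run
#'
#' Dispatches a [run_config()] to the corresponding pipeline, returns the
#' report (a list also written as JSON when `out` is set), and never leaves
#' a partial output file behind on error.  Every report echoes the full
#' effective configuration and seed.
#'
#' @param config A [run_config()].
#' @return The report, invisibly a list; `lambda = Inf` is serialized as
#'   the string `"inf"` in the JSON file.
#' @export
run_command <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config")
  # exact-name option lookup ($ would partially match, e.g. out/out_design)
  opt <- function(key, default = NULL) config[[key]] %||% default
  seed <- opt("seed", 1L)
  grid_size <- opt("grid_size", 100L)
  tol <- opt("tol", 1e-4)
  result <- switch(
    opt("command"),
    generate = {
      spec <- design_spec(opt("design", "iid"), opt("n"), opt("p"),
                          rho = opt("rho", 0.5),
                          decay = opt("decay", 1), seed = seed)
      x <- gen_design(spec)
      write_matrix(x, opt("out_design") %||% abort("need out_design"))
      written <- list(design = opt("out_design"))
      if (!is.null(opt("out_response"))) {
        y <- with_seed_opt(derive_seed(seed, 1L), rnorm(nrow(x)))
        write_matrix(matrix(y, dimnames = list(NULL, "y")),
                     opt("out_response"))
        written$response <- opt("out_response")
      }
      list(files = written, n = spec$n, p = spec$p, kind = spec$kind)
    },
    tune = {
      x <- read_matrix(opt("input"))
      model <- opt("model", "linear")
      grid <- NULL
      if (!is.null(opt("grid_size"))) {
        grid <- default_lambda_grid(design_spectrum(x),
                                    length = as.integer(grid_size))
      }
      fit <- if ((opt("test", "gt")) == "ft") {
        select_lambda_ft(x, read_response_vector(opt("response")),
                         opt("alpha"), grid = grid, tol = tol)
      } else {
        resp <- if (model == "cox") read_survival_file(opt("response")) else
          read_response_vector(opt("response"))
        select_lambda_gt(x, resp, opt("alpha"), model = model, grid = grid,
                         tol = tol)
      }
      as.list(glance(fit))
    },
    `gt-test` = {
      x <- read_matrix(opt("input"))
      model <- opt("model", "linear")
      resp <- if (model == "cox") read_survival_file(opt("response")) else
        read_response_vector(opt("response"))
      lam <- if (identical(opt("lambda"), "inf")) Inf else
        as.numeric(opt("lambda"))
      pv <- alpha_of_lambda(x, resp, lam, model = model)
      list(lambda = lam, p.value = pv, model = model)
    },
    `cox-tune` = {
      x <- read_matrix(opt("input"))
      surv <- read_survival_file(opt("response"))
      fit <- select_lambda_gt(x, surv, opt("alpha", 0.5), model = "cox",
                              tol = tol)
      as.list(glance(fit))
    },
    criteria = {
      x <- read_matrix(opt("input"))
      y <- read_response_vector(opt("response"))
      crit <- opt("criterion", "AIC")
      fit <- if (toupper(crit) %in% c("GCV", "LOOCV") ||
                 grepl("^[0-9]+-?CV$", toupper(crit))) {
        m <- parse_method(crit)
        cv_select(x, y, method = m$method, k = m$k %||%
                    as.integer(opt("folds", 5L)), seed = seed)
      } else {
        ic_select(x, y, crit)
      }
      as.list(glance(fit))
    },
    simulate = {
      scen <- simulation_scenario(
        design = design_spec(opt("design", "iid"), opt("n"), opt("p"),
                             rho = opt("rho", 0.5),
                             decay = opt("decay", 1),
                             seed = derive_seed(seed, 0L)),
        s = opt("s", 0), r2 = opt("r2", 0),
        reps = opt("reps", 100L), seed = seed
      )
      methods <- opt("methods", c("GT95", "GT50"))
      res <- if (scen$r2 == 0) run_null_experiment(scen, methods) else
        run_mse_experiment(scen, methods)
      if (!is.null(opt("out_table"))) {
        readr::write_tsv(res, opt("out_table"))
      }
      lapply(seq_len(nrow(res)), function(i) as.list(res[i, ]))
    }
  )
  report <- list(
    command = opt("command"),
    config = sanitize_report(unclass(config)),
    seed = seed,
    version = as.character(utils::packageVersion("gtridge")),
    result = result
  )
  write_report(report, opt("out"))
  invisible(report)
}
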