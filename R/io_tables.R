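# Tabular interchange: the docking-summary and capacity CSV dialects, the
# structured-text fitted-parameter file, and the capacity_panel container
# assembling them for fitting and validation. Output files carry '#' header
# comments recording the package version, seed, and key parameters, so every
# number in a result file is traceable to its configuration.

.header_lines <- function(seed = NULL, extra = character(0)) {
  version <- tryCatch(as.character(utils::packageVersion("ugtcap")),
                      error = function(e) "dev")
  c(sprintf("# ugtcap %s", version),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    extra)
}

.write_csv_with_header <- function(df, path, seed = NULL, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_lines(seed, extra), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write docking-summary tables
#'
#' Columns: `variant`, `ligand`, `S_DT`, `S_DH`, `udpga_correct_count`.
#' Lines starting with `#` are header comments.
#'
#' @param path CSV path.
#' @return `read_summary_csv`: a data frame with the columns above.
#' @export
read_summary_csv <- function(path) {
  df <- .read_csv_table(path)
  required <- c("variant", "ligand", "S_DT", "S_DH", "udpga_correct_count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("summary CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- df$S_DH > df$S_DT | df$S_DT <= 0 | df$S_DH < 0
  if (any(bad)) {
    stop("invalid pose counts for variant(s): ",
         paste(df$variant[bad], collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_summary_csv
#' @param df Data frame of docking summaries.
#' @param seed Optional seed recorded in the header.
#' @export
write_summary_csv <- function(df, path, seed = NULL) {
  .write_csv_with_header(df, path, seed)
}

#' Read and write in vitro capacity tables
#'
#' Columns: `variant`, `genotype`, `Vc`. Capacities are on any consistent
#' scale (the model's `sigma` absorbs units; the bundled convention is
#' percent of wild-type). The string `ND` (not detected) is read as `NA`
#' with `nd = TRUE`.
#'
#' @param path CSV path.
#' @return `read_capacity_csv`: data frame with `variant`, `genotype`,
#'   `V_c` (numeric, `NA` when not detected) and `nd` (logical).
#' @export
read_capacity_csv <- function(path) {
  df <- .read_csv_table(path)
  required <- c("variant", "genotype", "Vc")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("capacity CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nd <- toupper(trimws(as.character(df$Vc))) == "ND"
  v <- suppressWarnings(as.numeric(as.character(df$Vc)))
  bad <- which(!nd & is.na(v))
  if (length(bad) > 0L) {
    stop("capacity neither numeric nor ND for variant(s): ",
         paste(df$variant[bad], collapse = ", "), call. = FALSE)
  }
  if (any(v < 0, na.rm = TRUE)) stop("negative capacity", call. = FALSE)
  data.frame(variant = df$variant, genotype = df$genotype,
             V_c = ifelse(nd, NA_real_, v), nd = nd,
             stringsAsFactors = FALSE)
}

#' @rdname read_capacity_csv
#' @param df Data frame with `variant`, `genotype` and either `Vc` or
#'   `V_c`/`nd` columns.
#' @param seed Optional seed recorded in the header.
#' @export
write_capacity_csv <- function(df, path, seed = NULL) {
  if (is.null(df$Vc)) {
    df$Vc <- ifelse(is.na(df$V_c), "ND", format(df$V_c, trim = TRUE))
    df$V_c <- NULL
    df$nd <- NULL
  }
  .write_csv_with_header(df[, c("variant", "genotype", "Vc")], path, seed)
}

#' Write a result table with a provenance header
#'
#' Generic CSV writer used for derived tables (fold results, agreement
#' summaries): prepends `#` comment lines with the package version and the
#' seed so outputs are traceable to their configuration.
#'
#' @param df Data frame to write.
#' @param path CSV path.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path, seed = NULL) {
  .write_csv_with_header(df, path, seed)
}

#' Write a per-pose classification table
#'
#' Columns: `ligand_id`, `pose_index`, `min_hydroxyl_distance_A`,
#' `oriented` (0/1).
#'
#' @param counts Result of [count_orientations()].
#' @param ligand_id Ligand identifier for the table.
#' @param path CSV path.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_classification_csv <- function(counts, ligand_id, path, seed = NULL) {
  df <- cbind(ligand_id = ligand_id, counts$per_pose)
  .write_csv_with_header(df, path, seed)
}

#' Write and read fitted model constants as structured text
#'
#' A diffable `key: value` file holding the substrate name, the five model
#' constants, the fit SSE and the seed.
#'
#' @param fit A `capacity_fit` from [fit_parameters()].
#' @param ligand Substrate name recorded in the file.
#' @param path Output path.
#' @return `read_params_file`: list with `params` (a `model_params`),
#'   `ligand`, `sse`, and `seed`.
#' @export
write_params_file <- function(fit, ligand, path) {
  p <- fit$params
  lines <- c(
    .header_lines(fit$control$seed),
    sprintf("ligand: %s", ligand),
    sprintf("sigma: %.12g", p$sigma),
    sprintf("gamma: %.12g", p$gamma),
    sprintf("mu: %.12g", p$mu),
    sprintf("epsilon: %.12g", p$epsilon),
    sprintf("beta: %.12g", p$beta),
    sprintf("sse: %.12g", fit$sse),
    sprintf("seed: %d", fit$control$seed)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params_file
#' @export
read_params_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  names(vals) <- keys
  num <- function(k) as.numeric(vals[[k]])
  list(
    params = model_params(sigma = num("sigma"), gamma = num("gamma"),
                          mu = num("mu"), epsilon = num("epsilon"),
                          beta = num("beta")),
    ligand = vals[["ligand"]],
    sse = num("sse"),
    seed = as.integer(vals[["seed"]])
  )
}

#' Assemble a capacity panel for one substrate
#'
#' Joins docking summaries with in vitro capacities for one ligand and
#' separates the wild-type entry (which anchors `beta` and the relative
#' scale) from the mutant members.
#'
#' @param summaries Data frame as from [read_summary_csv()].
#' @param capacities Data frame as from [read_capacity_csv()].
#' @param ligand Substrate to select.
#' @param wild_name Variant name identifying the wild-type row.
#' @return An object of class `capacity_panel`: list with `ligand`,
#'   `wild_summary` (a `docking_summary`), `wild_capacity` (numeric),
#'   and `members`, a data frame with columns `variant`, `genotype`,
#'   `S_DT`, `S_DH`, `udpga_correct_count`, `V_c`, `nd`.
#' @export
capacity_panel <- function(summaries, capacities, ligand = NULL,
                           wild_name = "wild") {
  if (!is.null(ligand)) summaries <- summaries[summaries$ligand == ligand, ]
  if (nrow(summaries) == 0L) stop("no summaries for ligand ", ligand, call. = FALSE)
  if (is.null(ligand)) ligand <- summaries$ligand[1]
  merged <- merge(summaries, capacities, by = "variant", all.x = TRUE)
  if (is.null(merged$nd)) merged$nd <- is.na(merged$V_c)

  wild_row <- merged[merged$variant == wild_name, ]
  if (nrow(wild_row) != 1L) {
    stop("panel needs exactly one wild-type row named '", wild_name, "'",
         call. = FALSE)
  }
  if (wild_row$S_DH <= 0) {
    stop("wild-type has no oriented poses; panel unusable", call. = FALSE)
  }
  members <- merged[merged$variant != wild_name, , drop = FALSE]
  rownames(members) <- NULL
  structure(list(
    ligand = ligand,
    wild_summary = docking_summary(wild_name, ligand, wild_row$S_DT,
                                   wild_row$S_DH, wild_row$udpga_correct_count),
    wild_genotype = if (is.na(wild_row$genotype)) "wild/wild" else wild_row$genotype,
    wild_capacity = wild_row$V_c,
    members = members[, c("variant", "genotype", "S_DT", "S_DH",
                          "udpga_correct_count", "V_c", "nd")]
  ), class = "capacity_panel")
}

#' @export
print.capacity_panel <- function(x, ...) {
  cat(sprintf("<capacity_panel> ligand '%s': wild + %d members (%d in fit set)\n",
              x$ligand, nrow(x$members), nrow(fit_set(x))))
  invisible(x)
}

#' Fit set M of a panel
#'
#' The variants whose in vitro capacity is known and whose coenzyme attains
#' the correct binding mode. Not-detected capacities are censored
#' observations and excluded unless `include_nd = TRUE` (which enters them
#' as 0).
#'
#' @param panel A `capacity_panel`.
#' @param include_nd Enter ND capacities as 0.
#' @return The member rows forming the fit set.
#' @export
fit_set <- function(panel, include_nd = FALSE) {
  m <- panel$members
  if (include_nd) {
    m$V_c[m$nd] <- 0
  }
  keep <- !is.na(m$V_c) & m$udpga_correct_count > 0
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop one member from a panel
#'
#' @param panel A `capacity_panel`.
#' @param variant Name of the member to exclude.
#' @return The reduced panel.
#' @export
drop_member <- function(panel, variant) {
  keep <- panel$members$variant != variant
  if (all(keep)) stop("variant not in panel: ", variant, call. = FALSE)
  panel$members <- panel$members[keep, , drop = FALSE]
  rownames(panel$members) <- NULL
  panel
}

#' Predict relative capacities for every panel member
#'
#' Applies [predict_relative()] across the panel, flagging members predicted
#' 0 by the no-coenzyme-binding rule.
#'
#' @param panel A `capacity_panel`.
#' @param params A `model_params`.
#' @param kappa_mode Passed to [kappa()].
#' @return Data frame with `variant`, `genotype`, `fraction`,
#'   `predicted_pct`, `no_udpga_binding`.
#' @export
predict_panel <- function(panel, params, kappa_mode = "printed") {
  m <- panel$members
  out <- lapply(seq_len(nrow(m)), function(i) {
    s <- docking_summary(m$variant[i], panel$ligand, m$S_DT[i], m$S_DH[i],
                         m$udpga_correct_count[i])
    p <- predict_relative(s, m$genotype[i], params, panel$wild_summary,
                          kappa_mode)
    data.frame(variant = m$variant[i], genotype = m$genotype[i],
               fraction = m$S_DH[i] / m$S_DT[i],
               predicted_pct = as.numeric(p),
               no_udpga_binding = attr(p, "no_udpga_binding"))
  })
  do.call(rbind, out)
}
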