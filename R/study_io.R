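#' Define a balanced line x tester trial design
#'
#' A line x tester design crosses each of `l` female lines with each of `t`
#' male testers, and evaluates the `l + t` parents and `l * t` crosses
#' (optionally alongside check entries) in `r` complete replications.
#'
#' @param lines Character vector of line (female parent) identifiers.
#' @param testers Character vector of tester (male parent) identifiers.
#' @param n_reps Number of complete replications (at least 2).
#' @param checks Optional character vector of check-entry identifiers.
#' @return An object of class `"trial_design"`: a list with elements
#'   `lines`, `testers`, `n_reps`, `checks`, `l`, `t`, `r`.
#' @examples
#' trial_design(paste0("L", 1:20), paste0("T", 1:6), 3)
#' @export
trial_design <- function(lines, testers, n_reps, checks = character()) {
  lines <- as.character(lines)
  testers <- as.character(testers)
  checks <- as.character(checks)
  if (length(lines) < 2L) stop("need at least 2 lines")
  if (length(testers) < 2L) stop("need at least 2 testers")
  if (n_reps < 2L) stop("need at least 2 replications")
  all_ids <- c(lines, testers, checks)
  if (anyDuplicated(all_ids))
    stop("identifiers must be unique across lines, testers and checks: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  structure(list(lines = lines, testers = testers,
                 n_reps = as.integer(n_reps), checks = checks,
                 l = length(lines), t = length(testers),
                 r = as.integer(n_reps)),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Line x tester design: ", x$l, " lines x ", x$t, " testers, ",
      x$r, " reps", sep = "")
  if (length(x$checks)) cat(", ", length(x$checks), " checks", sep = "")
  cat("\n  entries: ", x$l + x$t, " parents + ", x$l * x$t, " crosses\n",
      sep = "")
  invisible(x)
}

#' Default trait list for a cauliflower yield trial
#'
#' Sixteen standard vegetative and commercial traits with units; used as the
#' default trait set by the readers and simulators.
#'
#' @return A data.frame with columns `trait`, `unit`, `desirable`
#'   (direction `"+"` or `"-"` for heterosis ranking).
#' @export
default_traits <- function() {
  data.frame(
    trait = c("CI", "CM", "PH", "GPW", "MCW", "NCW", "LL", "LW",
              "NoL", "CL", "CD", "CoL", "CSI", "LSI", "HI", "TMY"),
    unit = c("days", "days", "cm", "g", "g", "g", "cm", "cm",
             "count", "cm", "cm", "cm", "cm2", "cm2", "%", "t/ha"),
    desirable = c("-", "-", "+", "+", "+", "+", "+", "+",
                  "+", "+", "+", "-", "+", "+", "+", "+"),
    stringsAsFactors = FALSE
  )
}

valid_roles <- c("line_parent", "tester_parent", "cross", "check")

validate_records <- function(records, design, traits) {
  req <- c("entry", "role", "line", "tester", "rep", "block")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  bad_role <- which(!records$role %in% valid_roles)
  if (length(bad_role))
    stop("unknown role '", records$role[bad_role[1]], "' at row ",
         bad_role[1])
  cr <- records$role == "cross"
  bad_line <- cr & !records$line %in% design$lines
  if (any(bad_line))
    stop("cross references undeclared line parent '",
         records$line[which(bad_line)[1]], "' at row ", which(bad_line)[1])
  bad_tst <- cr & !records$tester %in% design$testers
  if (any(bad_tst))
    stop("cross references undeclared tester parent '",
         records$tester[which(bad_tst)[1]], "' at row ", which(bad_tst)[1])
  key <- paste(records$entry, records$rep)
  if (anyDuplicated(key))
    stop("duplicate (entry, rep) rows: ", key[which(duplicated(key))[1]])
  for (tr in traits) {
    if (!tr %in% names(records)) stop("trait column '", tr, "' not found")
    v <- records[[tr]]
    if (!is.numeric(v))
      stop("non-numeric values in trait column '", tr, "'")
  }
  invisible(records)
}

#' Read a plot-level phenotype table
#'
#' Reads a CSV of raw plot observations from a line x tester trial. The file
#' must contain the columns `entry`, `role`, `line`, `tester`, `rep`,
#' `block`, followed by one numeric column per trait. Roles are one of
#' `line_parent`, `tester_parent`, `cross`, `check`; for crosses the `line`
#' and `tester` columns name the two parents. The design (line, tester and
#' check identifier sets, replicate count) is inferred from the records.
#'
#' @param path Path to the CSV file.
#' @param traits Character vector of trait column names; default: every
#'   column after `block`.
#' @return An object of class `"lt_trial"`: a list with elements `design`
#'   (a [trial_design()]), `records` (validated data.frame) and `traits`.
#' @seealso [write_phenotypes()], [entry_means()], [lt_anova()]
#' @export
read_phenotypes <- function(path, traits = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (nrow(df) == 0L) stop("empty phenotype file: ", path)
  for (col in c("entry", "role", "line", "tester"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  if (is.null(traits)) {
    i <- match("block", names(df))
    if (is.na(i)) stop("missing required column: block")
    traits <- names(df)[seq.int(i + 1L, length(names(df)))]
  }
  # trait cells must parse as numbers; report the offending row
  for (tr in traits) {
    v <- df[[tr]]
    if (is.null(v)) stop("trait column '", tr, "' not found")
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA" & v != "")
      if (length(bad))
        stop("non-numeric trait value '", v[bad[1]], "' in column '", tr,
             "' at row ", bad[1])
      df[[tr]] <- num
    }
  }
  lines <- unique(df$entry[df$role == "line_parent"])
  testers <- unique(df$entry[df$role == "tester_parent"])
  # crosses-only files: fall back to the parent ids the crosses name
  if (length(lines) == 0L) lines <- unique(df$line[df$role == "cross"])
  if (length(testers) == 0L)
    testers <- unique(df$tester[df$role == "cross"])
  checks <- unique(df$entry[df$role == "check"])
  design <- trial_design(lines, testers, max(df$rep), checks)
  validate_records(df, design, traits)
  structure(list(design = design, records = df, traits = traits),
            class = "lt_trial")
}

#' @export
print.lt_trial <- function(x, ...) {
  print(x$design)
  cat("  ", nrow(x$records), " plot records, ", length(x$traits),
      " traits\n", sep = "")
  invisible(x)
}

#' Write a plot-level phenotype table
#'
#' Inverse of [read_phenotypes()]; round-trips exactly.
#'
#' @param trial An `"lt_trial"` object (or a bare records data.frame).
#' @param path Output CSV path.
#' @export
write_phenotypes <- function(trial, path) {
  rec <- if (inherits(trial, "lt_trial")) trial$records else trial
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check record counts of a balanced trial
#'
#' A complete balanced trial contains `(l + t + l*t + n_checks) * r` plot
#' records, one per entry per replicate.
#'
#' @param records Plot-record data.frame.
#' @param design A [trial_design()].
#' @return A list with `expected`, `observed`, `balanced` (logical) and
#'   `missing` / `extra` entry-by-rep keys.
#' @export
check_balance <- function(records, design) {
  entries <- c(design$lines, design$testers,
               as.vector(outer(design$lines, design$testers, paste,
                               sep = "x")),
               design$checks)
  cross_id <- ifelse(records$role == "cross",
                     paste(records$line, records$tester, sep = "x"),
                     records$entry)
  want <- as.vector(outer(entries, seq_len(design$r), paste, sep = "@"))
  have <- paste(cross_id, records$rep, sep = "@")
  list(expected = length(want), observed = nrow(records),
       balanced = setequal(want, have) && !anyDuplicated(have),
       missing = setdiff(want, have), extra = setdiff(have, want))
}

#' Per-entry trait means over replicates
#'
#' Arithmetic mean of each entry's plot values over its replicates; missing
#' plots reduce the divisor. Entry means are the analysis unit for combining
#' ability and heterosis.
#'
#' @param records Plot-record data.frame (or an `"lt_trial"`).
#' @param trait Trait column name.
#' @return A data.frame with columns `entry`, `role`, `line`, `tester`,
#'   `mean`, `n`.
#' @export
entry_means <- function(records, trait) {
  if (inherits(records, "lt_trial")) records <- records$records
  if (!trait %in% names(records))
    stop("trait '", trait, "' absent from records")
  sp <- split(seq_len(nrow(records)), records$entry)
  out <- lapply(sp, function(i) {
    v <- records[[trait]][i]
    data.frame(entry = records$entry[i[1]], role = records$role[i[1]],
               line = records$line[i[1]], tester = records$tester[i[1]],
               mean = mean(v, na.rm = TRUE), n = sum(!is.na(v)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$entry, unique(records$entry))), , drop = FALSE]
}

#' Read a codominant genotype table
#'
#' Reads an individuals x loci SSR genotype CSV in one of two dialects:
#' `"two_column"` (two adjacent columns `<locus>.1`, `<locus>.2` per locus)
#' or `"slash_pair"` (one `a/b` column per locus). The first column holds
#' individual identifiers. A configurable token marks missing calls; a call
#' with exactly one missing allele is rejected.
#'
#' @param path Path to the CSV file.
#' @param dialect `"two_column"` or `"slash_pair"`.
#' @param missing Missing-data token (default `"NA"`).
#' @return An object of class `"genotype_matrix"`: list with `ids`, `loci`,
#'   and character matrices `a1`, `a2` (NA = missing call).
#' @export
read_genotypes <- function(path, dialect = c("two_column", "slash_pair"),
                           missing = "NA") {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", na.strings = NULL)
  if (nrow(df) == 0L) stop("empty genotype file: ", path)
  ids <- df[[1]]
  body <- df[-1]
  if (dialect == "slash_pair") {
    loci <- names(body)
    a1 <- a2 <- matrix(NA_character_, nrow(df), length(loci),
                       dimnames = list(ids, loci))
    for (j in seq_along(loci)) {
      cell <- trimws(body[[j]])
      is_mis <- cell == missing | cell == ""
      parts <- strsplit(cell, "/", fixed = TRUE)
      for (i in seq_along(cell)) {
        if (is_mis[i]) next
        p <- trimws(parts[[i]])
        if (length(p) != 2L)
          stop("malformed call '", cell[i], "' at individual ", ids[i],
               ", locus ", loci[j])
        if (xor(p[1] == missing, p[2] == missing))
          stop("half-missing call at individual ", ids[i], ", locus ",
               loci[j])
        if (p[1] != missing) { a1[i, j] <- p[1]; a2[i, j] <- p[2] }
      }
    }
  } else {
    if (ncol(body) %% 2L != 0L)
      stop("two_column dialect needs an even number of allele columns")
    odd <- seq(1L, ncol(body), by = 2L)
    loci <- sub("[._][12Aab]$", "", names(body)[odd])
    a1 <- a2 <- matrix(NA_character_, nrow(df), length(loci),
                       dimnames = list(ids, loci))
    for (k in seq_along(odd)) {
      x <- trimws(body[[odd[k]]]); y <- trimws(body[[odd[k] + 1L]])
      mx <- x == missing | x == ""; my <- y == missing | y == ""
      if (any(xor(mx, my)))
        stop("half-missing call at individual ",
             ids[which(xor(mx, my))[1]], ", locus ", loci[k])
      keep <- !mx
      a1[keep, k] <- x[keep]; a2[keep, k] <- y[keep]
    }
  }
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix: ", length(x$ids), " individuals x ",
      length(x$loci), " loci, ", sum(is.na(x$a1)), " missing calls\n",
      sep = "")
  invisible(x)
}

#' Write a codominant genotype table
#'
#' @param gm A `"genotype_matrix"`.
#' @param path Output CSV path.
#' @param dialect Output dialect, as in [read_genotypes()].
#' @param missing Missing-data token.
#' @export
write_genotypes <- function(gm, path,
                            dialect = c("two_column", "slash_pair"),
                            missing = "NA") {
  dialect <- match.arg(dialect)
  if (dialect == "slash_pair") {
    body <- matrix(missing, length(gm$ids), length(gm$loci),
                   dimnames = list(NULL, gm$loci))
    ok <- !is.na(gm$a1)
    body[ok] <- paste(gm$a1[ok], gm$a2[ok], sep = "/")
    df <- data.frame(id = gm$ids, body, check.names = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    cols <- list(id = gm$ids)
    for (j in seq_along(gm$loci)) {
      x <- gm$a1[, j]; y <- gm$a2[, j]
      x[is.na(x)] <- missing; y[is.na(y)] <- missing
      cols[[paste0(gm$loci[j], ".1")]] <- x
      cols[[paste0(gm$loci[j], ".2")]] <- y
    }
    df <- as.data.frame(cols, check.names = FALSE,
                        stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fixture_schemas <- list(
  mean_squares = c("source", "df"),
  variance_components = c("component"),
  locus_stats = c("locus", "Ho", "He", "N", "PIC")
)

#' Read a shipped reference table
#'
#' Reads one of the plain-text reference tables shipped under
#' `inst/extdata/` (published mean squares, variance components, or
#' per-locus diversity statistics), checking the schema's required columns.
#'
#' @param path CSV path; see `system.file("extdata", package = "linetester")`.
#' @param schema One of `"mean_squares"`, `"variance_components"`,
#'   `"locus_stats"`.
#' @return A data.frame with labels preserved as printed.
#' @export
read_fixture_table <- function(path,
                               schema = c("mean_squares",
                                          "variance_components",
                                          "locus_stats")) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty fixture file: ", path)
  need <- fixture_schemas[[schema]]
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fixture lacks required column(s) for schema '", schema, "': ",
         paste(miss, collapse = ", "))
  df
}
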