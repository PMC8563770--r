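# Two-stage FWHM-based sizing: a normal distribution is fitted to the
# cohort's eye-to-chin distances and three hard-shell size brackets are
# centred on the lower FWHM boundary, the maximum, and the upper FWHM
# boundary. Within each shell the same construction applied to the sigma
# values gives three nasal-profile brackets, yielding nine designs.

#' Fit a normal distribution by moments
#'
#' Location is the sample mean, scale the sample standard deviation (n - 1
#' denominator), and the full width at half maximum follows as
#' `2 sd sqrt(2 log 2)`.
#'
#' @param values Numeric vector with at least 3 distinct finite values.
#' @return An object of class `normal_fit`: list with `mu`, `sd`, `fwhm`, `n`.
#' @export
fit_normal <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 3L)
    stop("need at least 3 finite values to fit a normal distribution")
  if (length(unique(values)) < 2L)
    stop("degenerate scale: all values are identical")
  mu <- mean(values)
  sd <- stats::sd(values)
  if (sd <= 0 || !is.finite(sd))
    stop("degenerate scale: standard deviation is not positive")
  structure(list(mu = mu, sd = sd, fwhm = 2 * sd * sqrt(2 * log(2)),
                 n = length(values)),
            class = "normal_fit")
}

#' @export
print.normal_fit <- function(x, ...) {
  cat(sprintf("normal_fit: mu = %.4g, sd = %.4g, fwhm = %.4g (n = %d)\n",
              x$mu, x$sd, x$fwhm, x$n))
  invisible(x)
}

#' Build three FWHM-centred size brackets
#'
#' Brackets are centred at `mu - fwhm/2`, `mu`, and `mu + fwhm/2` of the
#' fitted normal and extend `half_width` either side of their centre. Labels
#' are assigned in ascending order of centre. Adjacent brackets may overlap
#' (they do whenever `half_width > fwhm/4`); non-adjacent brackets must not,
#' which bounds `half_width < fwhm/2`.
#'
#' @param values Numeric cohort values (mm for eye-to-chin, mm for sigma).
#' @param half_width Half-width of each bracket, same units as `values`.
#' @param labels Three bracket labels, ascending.
#' @return A `data.frame` of class `size_brackets` with columns `label`,
#'   `lower`, `upper`, `midpoint`, and the `normal_fit` as attribute `fit`.
#' @export
build_size_brackets <- function(values, half_width,
                                labels = c("Small", "Medium", "Large")) {
  if (length(labels) != 3L)
    stop("exactly three bracket labels are required")
  if (!is.finite(half_width) || half_width <= 0)
    stop("half_width must be positive")
  fit <- fit_normal(values)
  if (half_width >= fit$fwhm / 2)
    stop("half_width (", signif(half_width, 4), ") >= fwhm/2 (",
         signif(fit$fwhm / 2, 4),
         "): non-adjacent brackets would overlap")
  centres <- fit$mu + c(-1, 0, 1) * fit$fwhm / 2
  out <- data.frame(label = labels,
                    lower = centres - half_width,
                    upper = centres + half_width,
                    midpoint = centres,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  class(out) <- c("size_brackets", "data.frame")
  out
}

#' Overlap regions of adjacent size brackets
#'
#' @param brackets A `size_brackets` data frame (or compatible), ordered by
#'   midpoint.
#' @return Data frame with columns `pair`, `lower`, `upper` for each adjacent
#'   pair that intersects (possibly zero rows).
#' @export
bracket_overlaps <- function(brackets) {
  brackets <- brackets[order(brackets$midpoint), , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(brackets) - 1L)) {
    lo <- brackets$lower[i + 1L]
    hi <- brackets$upper[i]
    if (hi > lo)
      out <- rbind(out, data.frame(
        pair = paste(brackets$label[i], brackets$label[i + 1L], sep = "/"),
        lower = lo, upper = hi, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(pair = character(), lower = numeric(),
                      upper = numeric(), stringsAsFactors = FALSE)
  out
}

.validate_cohort <- function(cohort) {
  need <- c("subject_id", "eye_to_chin", "A", "sigma")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  num <- as.matrix(cohort[, c("eye_to_chin", "A", "sigma")])
  if (!all(is.finite(num)) || any(num <= 0))
    stop("cohort values must be positive and finite")
  invisible(cohort)
}

#' Build the nine-design sizing table from a cohort
#'
#' Stage one fits a normal distribution to the cohort eye-to-chin distances
#' and builds three hard-shell brackets ([build_size_brackets()]). Stage two
#' repeats the construction on the sigma values of each shell's members
#' (members in a shell/shell overlap contribute to both adjacent shells),
#' giving three nasal-profile brackets per shell. Mean `A` and mean `sigma`
#' are computed over the members of each of the nine (shell, profile) cells.
#'
#' @param cohort Data frame with columns `subject_id`, `eye_to_chin`, `A`,
#'   `sigma` (see [read_cohort()]).
#' @param shell_half_width Half-width of the eye-to-chin brackets, mm
#'   (default 4.5, calibrated to the bundled reference table).
#' @param profile_half_width Half-width of the sigma brackets (default 0.5).
#' @param min_cohort Cohort size below which a warning is issued.
#' @return An object of class `sizing_table`: list with `shell_brackets`
#'   (3-row data frame), `profiles` (9-row data frame with columns `shell`,
#'   `label`, `lower`, `upper`, `midpoint`, `sigma_mean`, `A_mean`, `n`),
#'   `overlap_regions`, and `config`.
#' @export
build_sizing_table <- function(cohort, shell_half_width = 4.5,
                               profile_half_width = 0.5, min_cohort = 30L) {
  .validate_cohort(cohort)
  if (nrow(cohort) < min_cohort)
    warning("cohort has only ", nrow(cohort),
            " records; bracket estimates will be unstable")
  shells <- build_size_brackets(cohort$eye_to_chin, shell_half_width,
                                labels = c("Small", "Medium", "Large"))
  profiles <- NULL
  for (i in seq_len(3L)) {
    lab <- shells$label[i]
    memb <- cohort[cohort$eye_to_chin >= shells$lower[i] &
                   cohort$eye_to_chin <= shells$upper[i], , drop = FALSE]
    if (nrow(memb) < 3L)
      stop("shell '", lab, "' has only ", nrow(memb),
           " members; cannot fit its sigma distribution")
    pb <- build_size_brackets(memb$sigma, profile_half_width,
                              labels = c("I", "II", "III"))
    for (j in seq_len(3L)) {
      cell <- memb[memb$sigma >= pb$lower[j] & memb$sigma <= pb$upper[j], ,
                   drop = FALSE]
      if (nrow(cell) == 0L)
        warning("cell ", lab, "(", pb$label[j], ") has no members; ",
                "mean A/sigma are NA")
      profiles <- rbind(profiles, data.frame(
        shell = lab, label = pb$label[j],
        lower = pb$lower[j], upper = pb$upper[j], midpoint = pb$midpoint[j],
        sigma_mean = if (nrow(cell)) mean(cell$sigma) else NA_real_,
        A_mean = if (nrow(cell)) mean(cell$A) else NA_real_,
        n = nrow(cell), stringsAsFactors = FALSE))
    }
  }
  sizing_table(shells, profiles,
               config = list(shell_half_width = shell_half_width,
                             profile_half_width = profile_half_width))
}

#' Construct a sizing table from bracket data
#'
#' Low-level constructor used by [build_sizing_table()] and the fixture
#' loader. Midpoints are recomputed as `(lower + upper) / 2` so the
#' `SizeBracket` invariant holds exactly.
#'
#' @param shell_brackets 3-row data frame with `label`, `lower`, `upper`.
#' @param profiles 9-row data frame with `shell`, `label`, `lower`, `upper`,
#'   and optionally `sigma_mean`, `A_mean`, `n`.
#' @param config Optional list of construction parameters.
#' @return A `sizing_table` object.
#' @export
sizing_table <- function(shell_brackets, profiles, config = list()) {
  shell_brackets <- as.data.frame(shell_brackets)
  profiles <- as.data.frame(profiles)
  shell_brackets$midpoint <- (shell_brackets$lower + shell_brackets$upper) / 2
  profiles$midpoint <- (profiles$lower + profiles$upper) / 2
  if (nrow(shell_brackets) != 3L)
    stop("exactly 3 shell brackets are required")
  if (nrow(profiles) != 9L)
    stop("exactly 9 (shell, profile) cells are required")
  if (any(shell_brackets$lower >= shell_brackets$upper) ||
      any(profiles$lower >= profiles$upper))
    stop("bracket lower bounds must be below their upper bounds")
  ord <- order(shell_brackets$midpoint)
  shell_brackets <- shell_brackets[ord, , drop = FALSE]
  rownames(shell_brackets) <- NULL
  if (!all(table(profiles$shell) == 3L) ||
      !setequal(unique(profiles$shell), shell_brackets$label))
    stop("each shell must have exactly 3 profile brackets")
  # non-adjacent shells must not overlap
  if (shell_brackets$upper[1] > shell_brackets$lower[3])
    stop("non-adjacent shell brackets overlap")
  structure(list(shell_brackets = shell_brackets,
                 profiles = profiles,
                 overlap_regions = bracket_overlaps(shell_brackets),
                 config = config),
            class = "sizing_table")
}

#' @export
print.sizing_table <- function(x, ...) {
  cat("sizing_table: 3 shells x 3 nasal profiles (9 designs)\n")
  cat("shell brackets (eye-to-chin, mm):\n")
  print(x$shell_brackets, row.names = FALSE)
  cat("profiles (sigma):\n")
  print(x$profiles, row.names = FALSE)
  if (nrow(x$overlap_regions)) {
    cat("shell overlap regions:\n")
    print(x$overlap_regions, row.names = FALSE)
  }
  invisible(x)
}

#' Load the bundled reference sizing table
#'
#' The package ships the nine-design reference table established from a
#' 200-participant calibration cohort (one-decimal printed limits). Midpoints
#' are recomputed from the limits.
#'
#' @return A `sizing_table`.
#' @export
load_reference_table <- function() {
  path <- system.file("extdata", "reference_sizing_table.csv",
                      package = "facefit", mustWork = TRUE)
  read_sizing_table(path)
}

#' Read a sizing table from CSV
#'
#' Expects the cell-per-row layout written by [write_sizing_table()]:
#' columns `shell`, `shell_lower`, `shell_upper`, `profile`, `sigma_lower`,
#' `sigma_upper`, `sigma_mean`, `A_mean`.
#'
#' @param path CSV path.
#' @return A `sizing_table`.
#' @export
read_sizing_table <- function(path) {
  if (!file.exists(path))
    stop("sizing table file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::fromJSON(path)
    return(sizing_table(lst$shell_brackets, lst$profiles,
                        config = as.list(lst$config)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("shell", "shell_lower", "shell_upper", "profile",
            "sigma_lower", "sigma_upper")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sizing table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  sh <- unique(df[, c("shell", "shell_lower", "shell_upper")])
  shells <- data.frame(label = sh$shell, lower = sh$shell_lower,
                       upper = sh$shell_upper, stringsAsFactors = FALSE)
  profiles <- data.frame(shell = df$shell, label = df$profile,
                         lower = df$sigma_lower, upper = df$sigma_upper,
                         sigma_mean = df$sigma_mean %||% NA_real_,
                         A_mean = df$A_mean %||% NA_real_,
                         stringsAsFactors = FALSE)
  sizing_table(shells, profiles)
}

#' Write a sizing table to CSV or JSON
#'
#' @param table A `sizing_table`.
#' @param path Output path; a `.json` suffix selects JSON, anything else the
#'   cell-per-row CSV layout.
#' @return `path`, invisibly.
#' @export
write_sizing_table <- function(table, path) {
  stopifnot(inherits(table, "sizing_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(shell_brackets = table$shell_brackets,
                              profiles = table$profiles,
                              config = table$config),
                         path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  sh <- table$shell_brackets
  pr <- table$profiles
  i <- match(pr$shell, sh$label)
  out <- data.frame(shell = pr$shell,
                    shell_lower = sh$lower[i], shell_upper = sh$upper[i],
                    shell_midpoint = sh$midpoint[i],
                    profile = pr$label,
                    sigma_lower = pr$lower, sigma_upper = pr$upper,
                    sigma_midpoint = pr$midpoint,
                    sigma_mean = pr$sigma_mean %||% NA_real_,
                    A_mean = pr$A_mean %||% NA_real_)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Assign a user to a semi-customised design or flag full customisation
#'
#' Stage one collects the shells whose eye-to-chin range contains the user's
#' value; none means the fully-customised route. A single shell proceeds to
#' stage two: the profile whose sigma range contains the user's sigma (none
#' again means fully customised). When the user falls in a shell overlap,
#' the shell is chosen by the closest sigma match: if sigma lies inside a
#' profile range of exactly one of the two shells that shell wins; if inside
#' both, the shell whose matching profile midpoint is closest to sigma wins
#' (ties: closer eye-to-chin midpoint, then the smaller shell); if inside
#' neither, the user is flagged for full customisation.
#'
#' @param params A [facial_parameters()] record, or any list with
#'   `eye_to_chin` and `sigma` elements.
#' @param table A `sizing_table`.
#' @return An object of class `assignment`: list with `route`
#'   (`"SEMI_CUSTOM"` or `"FULLY_CUSTOM"`), `shell`, `profile`, `in_overlap`,
#'   and `rationale` (character vector of rule applications).
#' @export
assign_design <- function(params, table) {
  stopifnot(inherits(table, "sizing_table"))
  ec <- params$eye_to_chin
  sg <- params$sigma
  if (!is.finite(ec) || !is.finite(sg) || ec <= 0 || sg <= 0)
    stop("eye_to_chin and sigma must be positive and finite")
  sh <- table$shell_brackets
  pr <- table$profiles
  rationale <- character()
  note <- function(...) rationale <<- c(rationale, sprintf(...))

  in_shell <- which(ec >= sh$lower & ec <= sh$upper)
  note("eye-to-chin %.2f mm lies in %d shell range(s): %s", ec,
       length(in_shell),
       if (length(in_shell)) paste(sh$label[in_shell], collapse = ", ")
       else "none")
  fully <- function() structure(list(route = "FULLY_CUSTOM", shell = NA_character_,
                                     profile = NA_character_,
                                     in_overlap = length(in_shell) == 2L,
                                     rationale = rationale),
                                class = "assignment")
  if (length(in_shell) == 0L) {
    note("outside all shell ranges: fully-customised route")
    return(fully())
  }
  pick_profile <- function(shell_label) {
    p <- pr[pr$shell == shell_label, , drop = FALSE]
    hit <- which(sg >= p$lower & sg <= p$upper)
    if (length(hit) == 0L) return(NULL)
    if (length(hit) > 1L)
      hit <- hit[order(abs(sg - p$midpoint[hit]), p$midpoint[hit])][1L]
    p[hit, , drop = FALSE]
  }
  if (length(in_shell) == 1L) {
    lab <- sh$label[in_shell]
    p <- pick_profile(lab)
    if (is.null(p)) {
      note("sigma %.2f lies outside all %s profile ranges: fully-customised route",
           sg, lab)
      return(fully())
    }
    note("sigma %.2f lies in %s profile %s [%.2f, %.2f]", sg, lab, p$label,
         p$lower, p$upper)
    return(structure(list(route = "SEMI_CUSTOM", shell = lab,
                          profile = p$label, in_overlap = FALSE,
                          rationale = rationale),
                     class = "assignment"))
  }
  # overlap between two adjacent shells: closest sigma match decides
  note("eye-to-chin falls in the %s/%s overlap region",
       sh$label[in_shell[1]], sh$label[in_shell[2]])
  cand <- lapply(sh$label[in_shell], pick_profile)
  has <- !vapply(cand, is.null, logical(1))
  if (!any(has)) {
    note("sigma %.2f lies outside the profile ranges of both shells: fully-customised route",
         sg)
    return(fully())
  }
  if (sum(has) == 1L) {
    k <- which(has)
    note("sigma %.2f fits a profile range of %s only", sg,
         sh$label[in_shell[k]])
  } else {
    d <- vapply(cand, function(p) abs(sg - p$midpoint), numeric(1))
    if (abs(d[1] - d[2]) > 1e-12) {
      k <- which.min(d)
      note("sigma %.2f is closer to the %s profile midpoint (%.3f vs %.3f)",
           sg, sh$label[in_shell[k]], d[k], d[-k][1])
    } else {
      de <- abs(ec - sh$midpoint[in_shell])
      k <- if (abs(de[1] - de[2]) > 1e-12) which.min(de) else 1L
      note("sigma distances tie; choosing %s by eye-to-chin midpoint/size order",
           sh$label[in_shell[k]])
    }
  }
  lab <- sh$label[in_shell[k]]
  p <- cand[[k]]
  note("assigned %s (%s)", lab, p$label)
  structure(list(route = "SEMI_CUSTOM", shell = lab, profile = p$label,
                 in_overlap = TRUE, rationale = rationale),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  if (x$route == "SEMI_CUSTOM")
    cat(sprintf("assignment: %s (%s)%s\n", x$shell, x$profile,
                if (x$in_overlap) " [from overlap region]" else ""))
  else
    cat("assignment: FULLY_CUSTOM (outside semi-customised ranges)\n")
  for (r in x$rationale) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Fraction of a cohort covered by the semi-customised designs
#'
#' With `rule = "joint"` (the rule used by [assign_design()]), a record is
#' covered when its eye-to-chin distance falls in at least one shell range
#' and its sigma falls in a profile range of such a shell — exactly the
#' records for which [assign_design()] returns `SEMI_CUSTOM`. With
#' `rule = "shell_only"`, coverage counts eye-to-chin within the cumulative
#' shell range only.
#'
#' @param cohort Cohort data frame (see [build_sizing_table()]).
#' @param table A `sizing_table`.
#' @param rule `"joint"` (default) or `"shell_only"`.
#' @return Fraction in `[0, 1]`.
#' @export
coverage <- function(cohort, table, rule = c("joint", "shell_only")) {
  rule <- match.arg(rule)
  stopifnot(inherits(table, "sizing_table"))
  .validate_cohort(cohort)
  if (nrow(cohort) == 0L)
    stop("cohort is empty")
  ec <- cohort$eye_to_chin
  if (rule == "shell_only") {
    lo <- min(table$shell_brackets$lower)
    hi <- max(table$shell_brackets$upper)
    return(mean(ec >= lo & ec <= hi))
  }
  sg <- cohort$sigma
  ok <- rep(FALSE, nrow(cohort))
  for (i in seq_len(3L)) {
    sh <- table$shell_brackets[i, ]
    p <- table$profiles[table$profiles$shell == sh$label, , drop = FALSE]
    in_sh <- ec >= sh$lower & ec <= sh$upper
    in_pr <- (sg >= p$lower[1] & sg <= p$upper[1]) |
             (sg >= p$lower[2] & sg <= p$upper[2]) |
             (sg >= p$lower[3] & sg <= p$upper[3])
    ok <- ok | (in_sh & in_pr)
  }
  mean(ok)
}

#' Agreement between two matched parameter sets
#'
#' For each shared numeric parameter: the mean absolute difference, that
#' difference as a percentage of the first set's mean, and the standard
#' deviation of the signed differences. Used to compare scanning methods on
#' the same subjects.
#'
#' @param setA,setB Data frames with a `subject_id` column and one column per
#'   parameter, matched by `subject_id`.
#' @return A data frame of class `agreement_summary` with one row per
#'   parameter: `parameter`, `mean_diff`, `mean_diff_pct`, `sd_diff`, `n`.
#' @export
compare_param_sets <- function(setA, setB) {
  setA <- as.data.frame(setA)
  setB <- as.data.frame(setB)
  if (!("subject_id" %in% names(setA)) || !("subject_id" %in% names(setB)))
    stop("both sets need a subject_id column")
  if (nrow(setA) != nrow(setB) ||
      !setequal(setA$subject_id, setB$subject_id) ||
      anyDuplicated(setA$subject_id))
    stop("subject_id mismatch between the two sets")
  setB <- setB[match(setA$subject_id, setB$subject_id), , drop = FALSE]
  pars <- intersect(names(setA), names(setB))
  pars <- pars[vapply(setA[pars], is.numeric, logical(1))]
  if (length(pars) == 0L)
    stop("no shared numeric parameter columns")
  out <- do.call(rbind, lapply(pars, function(p) {
    d <- setA[[p]] - setB[[p]]
    data.frame(parameter = p,
               mean_diff = mean(abs(d)),
               mean_diff_pct = 100 * mean(abs(d)) / mean(setA[[p]]),
               sd_diff = stats::sd(d),
               n = length(d), stringsAsFactors = FALSE)
  }))
  class(out) <- c("agreement_summary", "data.frame")
  out
}

#' Read a cohort CSV
#'
#' Columns `subject_id`, `eye_to_chin_mm`, `A_mm`, `sigma_mm` (the layout
#' written by [write_cohort()]).
#'
#' @param path CSV path.
#' @return Cohort data frame with columns `subject_id`, `eye_to_chin`, `A`,
#'   `sigma`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "eye_to_chin_mm", "A_mm", "sigma_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort file ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  out <- data.frame(subject_id = as.character(df$subject_id),
                    eye_to_chin = df$eye_to_chin_mm,
                    A = df$A_mm, sigma = df$sigma_mm,
                    stringsAsFactors = FALSE)
  .validate_cohort(out)
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data frame (internal column names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  .validate_cohort(cohort)
  utils::write.csv(data.frame(subject_id = cohort$subject_id,
                              eye_to_chin_mm = cohort$eye_to_chin,
                              A_mm = cohort$A, sigma_mm = cohort$sigma),
                   path, row.names = FALSE)
  invisible(path)
}
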