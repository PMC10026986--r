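#' Subject-by-condition coupling feature table
#'
#' Holds the condensed coupling features (one column per direction x
#' branch x band x channel, named e.g.
#' \code{heart_to_brain.SAI.beta.Cz.mad}) together with the stress
#' labels: \code{stress_level} encodes rest/stressors as 0, 1, 4, 5 and
#' \code{stress_class} groups rest + stressor 1 as \code{"low"} and
#' stressors 2 + 3 as \code{"high"}.
#'
#' @param features Data frame of feature columns (rows: subject x
#'   condition observations).
#' @param subject,condition Row annotations.
#' @param stress_level Numeric stress encoding per row.
#' @param stress_class \code{"low"} / \code{"high"} per row.
#' @return Object of class \code{feature_table}.
#' @export
feature_table <- function(features, subject, condition, stress_level,
                          stress_class) {
  features <- as.data.frame(features)
  if (anyNA(features))
    stop("feature table contains missing values; condensation failed ",
         "upstream for ", sum(!stats::complete.cases(features)), " row(s)")
  n <- nrow(features)
  stopifnot(length(subject) == n, length(condition) == n,
            length(stress_level) == n, length(stress_class) == n)
  structure(list(features = features, subject = subject,
                 condition = condition, stress_level = stress_level,
                 stress_class = stress_class),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table: ", nrow(x$features), " subject-condition rows x ",
      ncol(x$features), " coupling features\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

# flatten a feature_table (or compatible data frame) into a single data
# frame with an attribute naming the feature columns
as_feature_df <- function(table) {
  if (inherits(table, "feature_table")) {
    df <- cbind(data.frame(subject = table$subject,
                           condition = table$condition,
                           stress_level = table$stress_level,
                           stress_class = table$stress_class,
                           stringsAsFactors = FALSE),
                table$features)
    attr(df, "feature_cols") <- names(table$features)
    return(df)
  }
  df <- as.data.frame(table)
  meta <- intersect(c("subject", "condition", "stress_level",
                      "stress_class"), names(df))
  attr(df, "feature_cols") <- setdiff(names(df), meta)
  df
}

# decompose canonical feature identifiers into their components
parse_feature_names <- function(x) {
  parts <- strsplit(x, ".", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad))
    stop("malformed feature identifier: ", x[bad[1]])
  data.frame(feature = x,
             direction = vapply(parts, `[`, "", 1L),
             branch = vapply(parts, `[`, "", 2L),
             band = vapply(parts, `[`, "", 3L),
             channel = vapply(parts, `[`, "", 4L),
             tag = vapply(parts, `[`, "", 5L),
             stringsAsFactors = FALSE)
}

#' Read / write a feature table as delimited text
#'
#' Wide CSV with a header row of canonical feature identifiers plus the
#' \code{subject}, \code{condition}, \code{stress_level} and
#' \code{stress_class} columns.
#'
#' @param path File path.
#' @return \code{load_feature_table}: a [feature_table()].
#' @export
load_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  meta <- c("subject", "condition", "stress_level", "stress_class")
  if (!all(meta %in% names(df)))
    stop("missing annotation columns in ", path)
  feature_table(df[, setdiff(names(df), meta), drop = FALSE],
                df$subject, df$condition, df$stress_level,
                df$stress_class)
}

#' @rdname load_feature_table
#' @param x A [feature_table()].
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- as_feature_df(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
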