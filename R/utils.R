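#' @keywords internal
"_PACKAGE"

# delimiter lookup shared by all tabular readers/writers
.dialect_sep <- function(dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  if (dialect == "tab") "\t" else ","
}

# squeeze betas away from {0,1} so the logit is finite
.squeeze <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)

.clip01 <- function(x) pmin(pmax(x, 0), 1)

# Dirichlet draws via normalized gammas; rows sum to 1
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

.read_table <- function(path, dialect = "tab") {
  .stop_if(!file.exists(path), "file not found: ", path)
  utils::read.delim(path, sep = .dialect_sep(dialect), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA")
}

.write_table <- function(df, path, dialect = "tab", precise = FALSE) {
  if (precise) {  # 17 significant digits round-trip doubles bitwise
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x)
      ifelse(is.na(x), NA_character_, sprintf("%.17g", x)))
  }
  utils::write.table(df, path, sep = .dialect_sep(dialect), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
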