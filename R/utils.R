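# Internal helpers shared across modules.

# Fiscal calendar: month 1 = October, ..., month 12 = September.
fiscal_month <- function(date) {
  m <- as.integer(format(date, "%m"))
  ((m - 10L) %% 12L) + 1L
}

# Clip probabilities into (eps, 1 - eps); returns the vector with an
# attribute counting how many values were moved (logged by callers).
clip_probs <- function(p, eps = 1e-6) {
  clipped <- sum(p < eps | p > 1 - eps)
  out <- pmin(pmax(p, eps), 1 - eps)
  attr(out, "n_clipped") <- clipped
  out
}

# Derive a child seed from a master seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629) + 1L
}

assert_columns <- function(df, cols, table_name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(glue::glue(
      "table `{table_name}` is missing required column(s): ",
      "{paste(missing, collapse = ', ')}"
    ))
  }
  invisible(df)
}

# Factor constructors fixing the reference levels used throughout the
# estimation suite (quartile 1, physician, female, <30, White, 0, month 1).
fct_age_band <- function(age) {
  cut(age, breaks = c(-Inf, 30, 40, 50, Inf), right = FALSE,
      labels = c("<30", "30-39", "40-49", "50+"))
}

fct_elix_bin <- function(score) {
  if (any(score < 0)) {
    abort("negative Elixhauser score(s) found; scores must be non-negative counts")
  }
  factor(pmin(as.integer(score), 3L), levels = 0:3,
         labels = c("0", "1", "2", "3+"))
}

fct_race <- function(race) factor(race, levels = c("White", "Black", "Other"))
fct_gender <- function(gender) factor(gender, levels = c("Female", "Male"))
fct_provider_type <- function(type) factor(type, levels = c("physician", "pa_np"))
fct_fiscal_month <- function(m) factor(m, levels = 1:12)
fct_quartile <- function(q) factor(q, levels = 1:4)
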