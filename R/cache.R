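## Package-local memoization. Pathway graphs are tiny but requested many
## times with identical arguments (classification queries every loss/gain
## pair; simulation closes whole mixtures), so parsed congeners and
## pathway closures are cached. Keys include the rule-set content, not
## just its name, so user-defined rule sets never collide with built-ins.

.pkgCache <- new.env(parent = emptyenv())

.cacheGet <- function(key) {
  if (exists(key, envir = .pkgCache, inherits = FALSE))
    get(key, envir = .pkgCache, inherits = FALSE)
  else NULL
}

.cacheSet <- function(key, value) {
  assign(key, value, envir = .pkgCache)
  value
}

.rulesetKey <- function(rs) {
  paste(rs@name, rs@mode, rs@predicate,
        paste(rs@rules$substrate, rs@rules$removed, rs@rules$weight,
              sep = ":", collapse = ";"),
        sep = "|")
}
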