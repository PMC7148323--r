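# small populations for cheap tests
small_params <- function(n = 5000L, ...) dgp_params(pop_size = n, ...)

# a cohort spec built directly from proportions, bypassing the built-in table
make_spec <- function(proportions, n = 100L, name = "test", sex = "women",
                      model = default_within_category_model()) {
  structure(
    list(cohort = name, sex = sex, n = as.integer(n),
         proportions = proportions / sum(proportions),
         within_category_model = model),
    class = "cohort_spec"
  )
}
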