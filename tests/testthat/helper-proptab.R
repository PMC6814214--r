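# Shared fixtures and comparison helpers.

fig_table <- function() count_table(10, 30, 30, 20)

# canonical random-table panel for property tests (positive margins)
property_tables <- function(n = 1000, seed = 20240917) {
  random_tables(n, max_total = 200, seed = seed)
}

expect_rel <- function(object, expected, tol = 1e-10) {
  expect_true(all(abs(object - expected) <=
                    tol * pmax(1, abs(expected))),
              label = sprintf("max abs diff %.3g", max(abs(object - expected))))
}

row_table <- function(tab, i) {
  count_table(tab$a[i], tab$b[i], tab$c[i], tab$d[i])
}
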