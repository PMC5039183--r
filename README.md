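# hodgeflow

Information flow on small-world networks, decomposed.

`hodgeflow` studies how network topology shapes the *composition* of
information flow generated by dynamics on the network. It simulates
random threshold networks — binary ±1 units updating synchronously by
`x_i(t+1) = sgn(Σ_j w_ij x_j(t))` with random ±1 weights — on
Watts–Strogatz graphs, measures the information carried along each
causal link with the transfer entropy

    T_{j→i} = H(X_i(t+1) | X_i(t)) − H(X_i(t+1) | X_i(t), X_j(t))   [bits],

and applies the combinatorial Hodge decomposition to the resulting
skew-symmetric edge flow `e` (`e_ij = T_{i→j}` along causal links):

    e = g + h + c,   ‖e‖² = ‖g‖² + ‖h‖² + ‖c‖²,

with `g` a gradient flow (potential differences `f_j − f_i`; directed
transport), `h` harmonic (divergence-free and curl-free; global
circulation) and `c` curl (circulation around triangles; local
circulation). The ratios `γ, η, χ, λ = η + χ` quantify each component's
share; their topological counterparts `Γ = rank(G)/kN`,
`X = rank(C)/kN`, `H = 1 − Γ − X` are what a random flow would give, so
`γ < Γ` means the dynamics actively favors circulation. Sweeping the
rewiring probability `p` from lattice to random graph — through the
small-world region, tracked by the index `ω = L_r/L − C/C_c` — shows
the harmonic share rising, the curl share falling, and their sum peaking
inside the small-world band.

Intended for researchers in network/computational neuroscience and
complex systems who want a tested, reproducible implementation of this
pipeline or of any of its parts (WS generator with per-edge causal
directions, damage-spreading diagnostics, plug-in transfer entropy,
Hodge decomposition of arbitrary edge flows).

## Worked example

```r
library(hodgeflow)

net  <- ws_network(200, 3, p = 0.1, seed = 1)   # lattice + rewiring + directions
flow <- estimate_flow(net, n_realizations = 10, seed = 2)
comp <- hodge_decompose(flow, net)
comp
#> Hodge decomposition: ||e||^2 = 25.91
#>   gradient gamma = 0.2088  harmonic eta = 0.0739  curl chi = 0.7173  loop lambda = 0.7912

sr <- structural_ratios(net)
sprintf("structural: Gamma = %.4f  H = %.4f  X = %.4f", sr$Gamma, sr$H, sr$X)
#> "structural: Gamma = 0.3317  H = 0.0850  X = 0.5833"

sw <- small_world_index(net, n_ref = 20, seed = 3)
sprintf("L = %.3f  C = %.3f  omega = %.3f", sw$L, sw$C, sw$omega)
#> "L = 4.689  C = 0.495  omega = -0.155"
```

Reading: at `p = 0.1` this network is small-world (`ω = −0.155`, short
paths with lattice-like clustering `C ≈ 0.5`). The information flow is
dominated by local circulation (`χ = 0.72`, against a structural
baseline `X = 0.58`) while the gradient share sits well below its
structural level (`γ = 0.21` vs `Γ = 0.33`): the dynamics routes
information around loops rather than from sources to sinks.

`run_sweep(sweep_config(...))` repeats this over a grid of `p` and an
ensemble of networks; `damage_spreading(net, horizon)` verifies the
weakly chaotic regime (`δ_t > 0`); `hodge_decompose` works on any
user-supplied flow (`read_flow_tsv`). A command-line front end with the
same operations ships in `inst/cli/hodgeflow`.

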