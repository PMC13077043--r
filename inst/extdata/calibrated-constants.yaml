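CTC:
  ep_constants:
    alpha: 1.065182901794e+13
    N0: 1.065182901794e+12
    q: 2.46
    Vep: 0.258
    sigma_pore: auto
    r_star: 8.0e-10
    pore_dynamics: fixed_radius
    pore_diffusivity: 5.0e-14
    force_max: 7.0e-10
    r_h: 9.7e-10
    r_t: 3.1e-10
    line_tension: 1.8e-11
    surface_tension: 0.0
    temperature: 298.15
  medium:
    sigma_f: 0.015604793826
    eps_f: 80.0
    viscosity: 0.001
WBC:
  ep_constants:
    alpha: 289086220292.705078125
    N0: 28908622029.2705078125
    q: 2.46
    Vep: 0.258
    sigma_pore: auto
    r_star: 8.0e-10
    pore_dynamics: fixed_radius
    pore_diffusivity: 5.0e-14
    force_max: 7.0e-10
    r_h: 9.7e-10
    r_t: 3.1e-10
    line_tension: 1.8e-11
    surface_tension: 0.0
    temperature: 298.15
  medium:
    sigma_f: 0.009042567585
    eps_f: 80.0
    viscosity: 0.001
PLT:
  ep_constants:
    alpha: 1000000000.0
    N0: 100000000.0
    q: 2.46
    Vep: 0.258
    sigma_pore: auto
    r_star: 8.0e-10
    pore_dynamics: energy_ode
    pore_diffusivity: 2.255474198732e-13
    force_max: 7.0e-10
    r_h: 9.7e-10
    r_t: 3.1e-10
    line_tension: 1.8e-11
    surface_tension: 0.0
    temperature: 298.15
  medium:
    sigma_f: 0.013122053776
    eps_f: 80.0
    viscosity: 0.001
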