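# Synthetic study design: 13 grylloblattodean genera, 28 species outlines
# (8 monotypic fossil genera; extant genera with 10/5/3/1/1 species).
# coeffs: Fourier radius harmonics, interleaved (a1, b1, a2, b2, a3, b3, a4, b4).
# The five extant genus means sit in one compact shape family; fossil means
# are dispersed. All shapes are synthetic stand-ins for the digitized
# pronotum outlines, which are not publicly deposited.
within_genus_sd: 0.008
landmark_jitter_sd: 0.002
nuisance: true
k_semilandmarks: 50
n_vertices: 200
seed: 1
genera:
  - name: Blattogryllulus
    status: fossil
    species: [mongolicus]
    coeffs: [0.00, 0.00, -0.10, 0.00, 0.05, 0.00, 0.02, 0.00]
  - name: Parasheimia
    status: fossil
    species: [truncata]
    coeffs: [0.20, 0.00, 0.05, 0.05, 0.00, 0.00, 0.00, 0.05]
  - name: Plesioblattogryllus
    status: fossil
    species: [magnificus]
    coeffs: [-0.15, 0.05, 0.10, 0.00, -0.05, 0.00, 0.03, 0.00]
  - name: Sojanorapbidia
    status: fossil
    species: [martynovae]
    coeffs: [0.05, 0.15, -0.05, 0.10, 0.00, 0.00, -0.04, 0.00]
  - name: Sylvamicropteron
    status: fossil
    species: [harpax]
    coeffs: [-0.05, -0.12, 0.20, 0.00, 0.04, 0.04, 0.00, 0.00]
  - name: Sylvonympha
    status: fossil
    species: [tshekardensis]
    coeffs: [0.10, -0.08, -0.12, -0.06, 0.00, 0.00, 0.05, 0.00]
  - name: Tataronympha
    status: fossil
    species: [kamensis]
    coeffs: [-0.18, 0.00, 0.00, 0.12, 0.06, 0.00, -0.03, 0.00]
  - name: Tillyardembia
    status: fossil
    species: [antennaeplana]
    coeffs: [0.00, 0.10, 0.18, -0.08, -0.04, 0.00, 0.00, -0.04]
  - name: Galloisiana
    status: extant
    species: [chujoi, kiyosawai, kosuensis, nipponensis, odaesanensis,
              olgae, sinensis, ussuriensis, yezoensis, yuasai]
    coeffs: [0.07, 0.00, 0.17, 0.00, 0.02, 0.00, 0.06, 0.00]
  - name: Grylloblatta
    status: extant
    species: [barberi, campodeiformis, chandleri, gurneyi, sculleni]
    coeffs: [0.03, 0.01, 0.15, 0.00, 0.04, 0.00, 0.05, 0.00]
  - name: Grylloblattella
    status: extant
    species: [cheni, pravdini, sayanensis]
    coeffs: [0.05, -0.02, 0.13, 0.00, 0.02, 0.01, 0.05, 0.00]
  - name: Grylloblattina
    status: extant
    species: [djakonovi]
    coeffs: [0.06, 0.02, 0.15, 0.015, 0.01, 0.00, 0.05, 0.00]
  - name: Namkungia
    status: extant
    species: [biryongensis]
    coeffs: [0.04, -0.015, 0.165, -0.01, 0.02, 0.00, 0.06, 0.00]
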