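# Example AOI scheme for a 1280x960 scene: building area (A), bricks (B),
# manual (C); everything else is whitespace (W).
whitespace_letter: W
regions:
  - letter: A
    name: building area
    rect: [200, 200, 700, 700]
  - letter: B
    name: bricks
    rect: [750, 200, 1150, 600]
  - letter: C
    name: manual
    rect: [750, 650, 1150, 930]
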