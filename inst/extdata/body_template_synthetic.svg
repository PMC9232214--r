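<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic 2D body template (coronal front and back views). This is a
     minimal stand-in outline drawn for documentation and testing; it is not
     a digitized clinical template. Coordinates are template pixels, origin
     top left, y increasing downward. -->
<svg xmlns="http://www.w3.org/2000/svg" width="440" height="420"
     viewBox="0 0 440 420">
  <g id="body-template" fill="none" stroke="#000000" stroke-width="2">
    <g id="region-front" data-template-region="front">
      <circle cx="110" cy="40" r="25"/>
      <path d="M 85 70 L 70 90 L 55 180 L 70 185 L 85 110 L 85 230
               L 75 380 L 95 380 L 105 250 L 115 250 L 125 380 L 145 380
               L 135 230 L 135 110 L 150 185 L 165 180 L 150 90 L 135 70 Z"/>
    </g>
    <g id="region-back" data-template-region="back">
      <circle cx="330" cy="40" r="25"/>
      <path d="M 305 70 L 290 90 L 275 180 L 290 185 L 305 110 L 305 230
               L 295 380 L 315 380 L 325 250 L 335 250 L 345 380 L 365 380
               L 355 230 L 355 110 L 370 185 L 385 180 L 370 90 L 355 70 Z"/>
    </g>
  </g>
</svg>
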