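id	age	sex	site	segment	field	printed	curated	justification
C01	adult	male	Clavicle	Ends	b	240	24	Printed width 240 mm exceeds the stated database-wide maximum linear dimension (88 mm); the female analogue is 21-24 mm; decimal-point slip.
C02	adult	male	Sternum	Manubrium	h	1.3	13	Sternum plate heights printed one decade too small; the 15-year sternum height is 10.6 mm and a 1.3 mm manubrium is anatomically impossible; x10 transcription slip.
C03	adult	male	Sternum	Sternum bdoy	h	1.0	10	Same x10 transcription slip as the adult manubrium.
C04	adult	female	Sternum	Manubrium	h	1.1	11	Same x10 transcription slip as the adult male sternum plates.
C05	adult	female	Sternum	Body	h	0.9	9	Same x10 transcription slip as the adult male sternum plates.
C06	adult	male	Sternum	Sternum bdoy	segment	Sternum bdoy	Sternum body	Misspelling of "body".
C07	adult	male	Clavicle	Acromial shaft	c_ax	12	NA	Row is a cylinder; upper-base axes are not defined for that shape; stray carry-over from the neighbouring deformed-cylinder rows.
C08	adult	male	Clavicle	Acromial shaft	d_ax	12	NA	See C07.
C09	adult	female	Clavicle	Acromial shaft	c_ax	10	NA	See C07 (female analogue).
C10	adult	female	Clavicle	Acromial shaft	d_ax	10	NA	See C07 (female analogue).
C11	1y	any	Humerus	Shaft	c_ax	9.1	NA	Row is a cylinder; stray repeat of the shaft diameter in the upper-base column.
C12	1y	any	Pelvis	Ilium acetabular part	c_ax	24	NA	Row is printed as a cylinder; upper-base axes undefined; keeping the printed shape preserves the printed per-age shape census.
C13	1y	any	Pelvis	Ilium acetabular part	d_ax	18	NA	See C12.
C14	1y	any	Pelvis	Ischium tuberosity	shape	b	c	Printed per-age shape census requires 13 cylinders and 15 boxes at this age; this is the only row with a square (12 x 12 mm) cross-section for which box/cylinder ambiguity is plausible.
C15	1y	any	Pelvis	Ischium tuberosity	cortical	ha:0.4;hb:0.4	lateral:0.4	Consequence of C14: the paired rectangular side faces of the box become the lateral surface of the cylinder.
C16	newborn	any	Hand and foot	Precarpal	h	NA	7.8	Printed row is shifted by one column (height cell empty, a spare value in the upper-base column); the three ellipsoid axes are 7.8 x 12 x 7.8 mm.
C17	newborn	any	Hand and foot	Precarpal	a	7.8	12	See C16.
C18	newborn	any	Hand and foot	Precarpal	b	12	7.8	See C16.
C19	newborn	any	Hand and foot	Precarpal	c_ax	7.8	NA	See C16.
C20	adult	female	Sacrum	Ala 3-4	c_ax	38.5	NA	Row is a triangular prism; the equal-side length is repeated in the upper-base column; the male analogue has no such value.
C21	adult	female	Sacrum	Ala 3-4	cortical	bh:1.5;ab1:1.5	bh:1.5;ch:1.5;abb1:1.5	Prisms have no ab faces; the printed face list is garbled; male analogue reads bh; ch; abb1.
C22	10y	any	Humery	Distal end	site	Humery	Humerus	Misspelling of the site name; required for active-marrow site matching.
C23	10y	any	Humery	Proximal end	site	Humery	Humerus	See C22.
C24	15y	any	Ribs	1, 2	sex_specific	FALSE	TRUE	Printed per-age census lists 18 sex-specific segments per sex at 15 y; the extracted male/female tables are print-identical for four more rows than the census allows, and the census fixes their shapes (three boxes, one cylinder); rib dimensions are sex-dimorphic below the printed precision (the adult rib rows differ by sex).
C25	15y	any	Ribs	11, 12	sex_specific	FALSE	TRUE	See C24.
C26	15y	any	Ribs	5,6,7,8	sex_specific	FALSE	TRUE	See C24.
C27	15y	any	Vertebra	C3-7 body	sex_specific	FALSE	TRUE	See C24; the adult cervical body rows differ by sex.
C28	adult	any	Scapula	Glenoid	sex_specific	FALSE	TRUE	Printed per-age census lists 24 sex-specific segments per sex for adults and 17 cylinders; one print-identical cylinder pair must be sex-specific; scapular dimensions are strongly sex-dimorphic.
C29	adult	male	Clavicle	Ends	c_ax	NA	26	Deformed-cylinder row printed without upper-base axes; read as the degenerate equal-bases case of the shape definition (upper base equal to the lower base).
C30	adult	male	Clavicle	Ends	d_ax	NA	24	See C29.
C31	adult	female	Clavicle	Ends	c_ax	NA	24	See C29 (female analogue).
C32	adult	female	Clavicle	Ends	d_ax	NA	21	See C29 (female analogue).
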