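sl	phenolic	formula	sources
1	Curcumin	C21H20O6	Turmeric
2	Gossypol	C30H30O8	Cotton Plant
3	6-Shogaol	C17H24O3	Ginger
4	6-Gingerol	C17H26O4	Ginger
5	Apigenin	C15H10O5	parsley, celery, rosemary, coriander, cloves, spinach
6	Baicalein	C15H10O5	Scutellaria Baicalein, Scutellaria lateriflora
7	Cyanidin	C15H11O6	cranberries
8	Delphinidin	C15H11O7	Grapes, Cran berries, Corn cord grapes, Pomegranates
9	Embelin	C17H26O4	Japanese Ardisia herb
10	Epigallocatechin	C22H18O11	Green Tea
11	Fisetin	C15H10O6	strawberry, apple, grapes, onion, cucumber
12	Genistein	C15H10O5	Fara beans, Soybeans, Psoralea Flemingia vestita, F.macrophylla, Coffe
13	Glabridin	C20H20O4	licorice(root extract)
14	Isoliquiritigenin	C15H12O4	Root of licorice (Glycyrrhiza uralensis)
15	Luteolin	C15H10O6	Cabbage, spinach, peppers
16	Pterostilbene	C16H16O3	Blueberries, almond, mulberries
17	Quercetin	C15H10O7	Fruits, Vegetables, Leaves and Grains
18	Resveratrol	C14H12O3	red and purple grapes, blueberries, cranberries, mulberries, peanuts, roots of Japanese knotweed
19	Rosmarinic	C18H16O8	rosemary, lemon balm, sage, basil
20	Silibinin	C25H22O10	Extract of Milk thistle seeds
21	Psoralidin	C20H16O5	Seeds of Psoralea corylifolia
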