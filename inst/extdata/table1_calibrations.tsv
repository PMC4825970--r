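name	clade_taxa	kind	mean	sd_or_offset	configurations	locality
Ceresopsis costalis	Reduviidae	normal	185	10	B1;B2;B3	Sogyuty, Kyrgyzstan
Koenisbergia herczeki	Lophocustus sp;Macrocephalus spp;Phymata spp	normal	45	7	B2;B3	Samland Peninsula, Russia
Praecoris dominicana	Ptilonemus femoralis;Ptilocerus sp	normal	37	5	B2;B3	La Toca Mine, Dominican Republic
Danzigia christelae	Emesaya incisa;Stenolemus sp;Stenolemoides arizonensis;Mangabea barbiger;Ploiaria hirticornia;Empicoris sp	normal	45	7	B3	Samland Peninsula, Russia
Danzigia christelae	Emesaya incisa;Stenolemus sp;Stenolemoides arizonensis;Mangabea barbiger;Ploiaria hirticornia;Empicoris sp	exponential	10.5	25	B2	Samland Peninsula, Russia
Paleoploiariola venosa	Ploiaria hirticornia;Empicoris sp	normal	32.5	5	B3	Cordillera Septentrional, Dominican Republic
Panstrongylus hispaniolae	Panstrongylus spp;T. dimidiata;T. longipennis;T. mazzottii;T. mexicana;T. pallidipennis;T. phyllosoma;T. picturata;T. ryckmani;T. bruneri;T. rubrofasciata;T. barberi;T. protracta;T. gerstaeckeri;T. lecticularia;T. recurva;T. rubida;T. sanguisuga;Linshcosteus sp;Pa. hirsuta	normal	37	5	B2;B3	La Toca Mine, Dominican Republic
Apicrenus fossilis	Arilus cristatus;Acanthiscium sp	normal	37	5	B2;B3	La Toca Mine, Dominican Republic
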