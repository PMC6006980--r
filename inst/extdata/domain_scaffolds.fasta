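>KS synthetic consensus-like scaffold
HKPWQYERWREINTGQCFCIDTACSSSHRQYADITGGWMGMRQHMSAHGTGTILINKISCNNNDIIMLPQKSNIGHLYVRCCRVNSHTKE
>AT synthetic consensus-like scaffold
HFSLVGMDTYHPDECHKIATQKSFHMVCYSGHSQGCYGEDLKWSCCIMIGFPWLAHPIHDEHTMDVNNFHDFWRAAVPGN
>DH synthetic consensus-like scaffold
PWAFFAHSMHSYEFLPHLPAYTRYQHRSTGLLAPFPMHETLFVWPQGLILRDESLILKGI
>ER synthetic consensus-like scaffold
QCEWFMPVVLAIDLIPVQFAMTPSELAHAAAGGVGLLAARLAWHVPEANLFQCHRKFNYARYGCQEYILC
>KR synthetic consensus-like scaffold
NMFLPDDWASGGTGGLGHSFLNCNKCDVDMGAWIMGTFNTGATCREPMLCRACIVFREHDIFGMGSLLIYKSYLTTVHLWLYDVQYANMP
>ACP synthetic consensus-like scaffold
REVQFNNVHRQMIMYLGIDSNELSMVCRHYNPPRNDGIDL
>TE synthetic consensus-like scaffold
HHSLKPISEVEKGVRGARRLGWSLGGWPRTAPQGQVRKYYMWFCHMFYFC
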